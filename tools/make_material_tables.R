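# One-off generator for R/materials-data.R: per-material channel attenuation
# tables on a fixed photon-energy grid. Compton from Klein-Nishina x electron
# density, pair production from an XCOM-style water table scaled by rho*<Z^2/A>,
# photoelectric from a parametrized Z^4.4/E^3.1 fit anchored at water 0.1 MeV.
# Run from the repo root: Rscript tools/make_material_tables.R > R/materials-data.R

elements <- data.frame(
  sym = c("H","C","N","O","Na","Mg","P","S","Cl","Ar","K","Ca"),
  Z   = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 18, 19, 20),
  A   = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 30.974, 32.060,
          35.450, 39.948, 39.098, 40.078)
)

comp <- list(
  water   = c(H = 0.1119, O = 0.8881),
  adipose = c(H = 0.114, C = 0.598, N = 0.007, O = 0.278, Na = 0.001,
              S = 0.001, Cl = 0.001),
  lung    = c(H = 0.103, C = 0.105, N = 0.031, O = 0.749, Na = 0.002,
              P = 0.002, S = 0.003, Cl = 0.003, K = 0.002),
  brain   = c(H = 0.107, C = 0.145, N = 0.022, O = 0.712, Na = 0.002,
              P = 0.004, S = 0.002, Cl = 0.003, K = 0.003),
  bone    = c(H = 0.034, C = 0.155, N = 0.042, O = 0.435, Na = 0.001,
              Mg = 0.002, P = 0.103, S = 0.003, Ca = 0.225),
  air     = c(C = 0.000124, N = 0.755268, O = 0.231781, Ar = 0.012827)
)
density <- c(water = 1.0, adipose = 0.95, lung = 0.26, brain = 1.04,
             bone = 1.92, air = 0.0012041)

wmean <- function(w, v) {
  idx <- match(names(w), elements$sym)
  sum(w * v[idx])
}
za   <- sapply(comp, wmean, v = elements$Z / elements$A)
z2a  <- sapply(comp, wmean, v = elements$Z^2 / elements$A)
z44a <- sapply(comp, wmean, v = elements$Z^4.4 / elements$A)

# PDG radiation length per element (g/cm^2), mixture by mass fractions
x0el <- 716.408 * elements$A / (elements$Z * (elements$Z + 1) *
                                log(287 / sqrt(elements$Z)))
x0 <- sapply(comp, function(w) {
  idx <- match(names(w), elements$sym)
  1 / sum(w / x0el[idx])
})

egrid <- c(0.05, 0.08, 0.10, 0.15, 0.20, 0.30, 0.511, 0.80,
           1.022, 1.25, 1.50, 2.00, 2.617, 3.00)

re <- 2.8179403262e-13   # classical electron radius, cm
NAv <- 6.02214076e23
kn_sigma <- function(E) {
  a <- E / 0.51099895
  2 * pi * re^2 * ((1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) -
    log(1 + 2 * a) / a) + log(1 + 2 * a) / (2 * a) -
    (1 + 3 * a) / (1 + 2 * a)^2)
}

# XCOM-style water pair-production mass coefficients (nuclear + triplet), cm^2/g
pair_water <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1.0e-5, 6.0e-5, 3.9e-4, 8.35e-4, 1.12e-3)
# water photoelectric anchor 2.6e-3 cm^2/g at 0.1 MeV, power-law in E
pe_water <- 2.6e-3 * (egrid / 0.1)^-3.1

fmt <- function(x) paste(sprintf("%.6e", x), collapse = ", ")

cat("# Embedded photon-interaction data (generated by tools/make_material_tables.R).\n")
cat("# Per-material linear attenuation coefficients (cm^-1) by channel on a fixed\n")
cat("# photon-energy grid; Compton from Klein-Nishina, pair production XCOM-style,\n")
cat("# photoelectric parametrized. Do not edit by hand.\n\n")
cat(".ppt_energy_grid <- c(", fmt(egrid), ")\n\n", sep = "")

cat(".ppt_material_data <- list(\n")
for (m in names(comp)) {
  rho <- density[[m]]
  mu_c  <- kn_sigma(egrid) * NAv * za[[m]] * rho
  mu_k  <- pair_water * (z2a[[m]] / z2a[["water"]]) * rho
  mu_pe <- pe_water * (z44a[[m]] / z44a[["water"]]) * rho
  cat(sprintf("  %s = list(\n", m))
  cat(sprintf("    density = %.7g,\n", rho))
  cat(sprintf("    z_over_a = %.6g,\n", za[[m]]))
  cat(sprintf("    x0_mass = %.6g,\n", x0[[m]]))
  cat("    mu_pe = c(", fmt(mu_pe), "),\n", sep = "")
  cat("    mu_compton = c(", fmt(mu_c), "),\n", sep = "")
  cat("    mu_pair = c(", fmt(mu_k), ")\n", sep = "")
  cat(sprintf("  )%s\n", if (m == "air") "" else ","))
}
cat(")\n")
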