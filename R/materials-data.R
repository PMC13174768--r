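# Embedded photon-interaction data (generated by tools/make_material_tables.R).
# Per-material linear attenuation coefficients (cm^-1) by channel on a fixed
# photon-energy grid; Compton from Klein-Nishina, pair production XCOM-style,
# photoelectric parametrized. Do not edit by hand.

.ppt_energy_grid <- c(5.000000e-02, 8.000000e-02, 1.000000e-01, 1.500000e-01, 2.000000e-01, 3.000000e-01, 5.110000e-01, 8.000000e-01, 1.022000e+00, 1.250000e+00, 1.500000e+00, 2.000000e+00, 2.617000e+00, 3.000000e+00)

.ppt_material_data <- list(
  water = list(
    density = 1,
    z_over_a = 0.55509,
    x0_mass = 36.3284,
    mu_pe = c(2.229289e-02, 5.192714e-03, 2.600000e-03, 7.397593e-04, 3.032357e-04, 8.627748e-05, 1.655269e-05, 4.124719e-06, 1.930526e-06, 1.034076e-06, 5.876117e-07, 2.408687e-07, 1.046603e-07, 6.853264e-08),
    mu_compton = c(1.877021e-01, 1.729196e-01, 1.647173e-01, 1.482897e-01, 1.358801e-01, 1.181523e-01, 9.578529e-02, 7.854300e-02, 6.985295e-02, 6.311908e-02, 5.735501e-02, 4.892530e-02, 4.180489e-02, 3.847302e-02),
    mu_pair = c(0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 1.000000e-05, 6.000000e-05, 3.900000e-04, 8.350000e-04, 1.120000e-03)
  ),
  adipose = list(
    density = 0.95,
    z_over_a = 0.555785,
    x0_mass = 41.5296,
    mu_pe = c(1.270940e-02, 2.960418e-03, 1.482286e-03, 4.217441e-04, 1.728777e-04, 4.918765e-05, 9.436853e-06, 2.351543e-06, 1.100612e-06, 5.895368e-07, 3.350033e-07, 1.373216e-07, 5.966786e-08, 3.907114e-08),
    mu_compton = c(1.785405e-01, 1.644795e-01, 1.566776e-01, 1.410518e-01, 1.292479e-01, 1.123854e-01, 9.111008e-02, 7.470938e-02, 6.644348e-02, 6.003829e-02, 5.455556e-02, 4.653729e-02, 3.976442e-02, 3.659519e-02),
    mu_pair = c(0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 7.943587e-06, 4.766152e-05, 3.097999e-04, 6.632895e-04, 8.896818e-04)
  ),
  lung = list(
    density = 0.26,
    z_over_a = 0.550483,
    x0_mass = 36.7836,
    mu_pe = c(6.108097e-03, 1.422768e-03, 7.123820e-04, 2.026889e-04, 8.308449e-05, 2.363943e-05, 4.535322e-06, 1.130145e-06, 5.289507e-07, 2.833296e-07, 1.610015e-07, 6.599636e-08, 2.867619e-08, 1.877747e-08),
    mu_compton = c(4.839757e-02, 4.458602e-02, 4.247112e-02, 3.823537e-02, 3.503566e-02, 3.046468e-02, 2.469751e-02, 2.025172e-02, 1.801105e-02, 1.627478e-02, 1.478856e-02, 1.261502e-02, 1.077907e-02, 9.919979e-03),
    mu_pair = c(0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 2.564393e-06, 1.538636e-05, 1.000113e-04, 2.141268e-04, 2.872120e-04)
  ),
  brain = list(
    density = 1.04,
    z_over_a = 0.55239,
    x0_mass = 37.0796,
    mu_pe = c(2.434377e-02, 5.670429e-03, 2.839193e-03, 8.078151e-04, 3.311325e-04, 9.421477e-05, 1.807549e-05, 4.504182e-06, 2.108129e-06, 1.129208e-06, 6.416703e-07, 2.630279e-07, 1.142887e-07, 7.483745e-08),
    mu_compton = c(1.942608e-01, 1.789617e-01, 1.704729e-01, 1.534712e-01, 1.406280e-01, 1.222808e-01, 9.913219e-02, 8.128743e-02, 7.229373e-02, 6.532457e-02, 5.935909e-02, 5.063483e-02, 4.326562e-02, 3.981734e-02),
    mu_pair = c(0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 1.014442e-05, 6.086654e-05, 3.956325e-04, 8.470594e-04, 1.136175e-03)
  ),
  bone = list(
    density = 1.92,
    z_over_a = 0.514787,
    x0_mass = 27.3081,
    mu_pe = c(3.117371e-01, 7.261336e-02, 3.635762e-02, 1.034457e-02, 4.240358e-03, 1.206479e-03, 2.314679e-04, 5.767884e-05, 2.699589e-05, 1.446020e-05, 8.216987e-06, 3.368236e-06, 1.463538e-06, 9.583399e-07),
    mu_compton = c(3.342218e-01, 3.079002e-01, 2.932952e-01, 2.640442e-01, 2.419477e-01, 2.103817e-01, 1.705550e-01, 1.398534e-01, 1.243800e-01, 1.123897e-01, 1.021262e-01, 8.711624e-02, 7.443766e-02, 6.850495e-02),
    mu_pair = c(0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 2.840582e-05, 1.704349e-04, 1.107827e-03, 2.371886e-03, 3.181452e-03)
  ),
  air = list(
    density = 0.0012041,
    z_over_a = 0.499185,
    x0_mass = 36.8619,
    mu_pe = c(2.699488e-05, 6.287954e-06, 3.148389e-06, 8.957884e-07, 3.671938e-07, 1.044750e-07, 2.004396e-08, 4.994700e-09, 2.337710e-09, 1.252182e-09, 7.115500e-10, 2.916724e-10, 1.267351e-10, 8.298746e-11),
    mu_compton = c(2.032496e-04, 1.872427e-04, 1.783610e-04, 1.605726e-04, 1.471352e-04, 1.279390e-04, 1.037193e-04, 8.504879e-05, 7.563893e-05, 6.834729e-05, 6.210578e-05, 5.297782e-05, 4.526762e-05, 4.165978e-05),
    mu_pair = c(0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 0.000000e+00, 1.207410e-08, 7.244459e-08, 4.708898e-07, 1.008187e-06, 1.352299e-06)
  )
)
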