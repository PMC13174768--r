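#' Event-log persistence
#'
#' Event logs are written as a gzip-compressed columnar text file (one row
#' per event with a type tag) plus a YAML sidecar holding the run metadata
#' and the first-interaction channel counts.
#'
#' @param log A `ppt_eventlog`.
#' @param path Output path ending in `.csv.gz`; the sidecar gets `.yaml`.
#' @return `path`, invisibly.
#' @export
write_eventlog <- function(log, path) {
  stopifnot(inherits(log, "ppt_eventlog"))
  rows <- dplyr::bind_rows(
    dplyr::mutate(log$pairs, type = "pair", .before = 1),
    dplyr::mutate(log$annihilations, type = "annihilation", .before = 1),
    if (nrow(log$photons))
      dplyr::mutate(log$photons, type = "photon", .before = 1)
  )
  con <- gzfile(path, "w")
  utils::write.csv(as.data.frame(rows), con, row.names = FALSE)
  close(con)
  side <- sub("\\.csv\\.gz$", ".yaml", path)
  yaml::write_yaml(list(
    n_primaries = log$n_primaries,
    first_channel_counts = as.list(stats::setNames(
      tabulate(log$first_channel + 1L, nbins = 4L),
      c("none", "photoelectric", "compton", "pair"))),
    seed = log$seed,
    grid_shape = log$grid_shape, voxel_mm = log$voxel_mm,
    config = unclass(log$config)), side)
  invisible(path)
}

#' @rdname write_eventlog
#' @export
read_eventlog <- function(path) {
  side <- sub("\\.csv\\.gz$", ".yaml", path)
  meta <- yaml::read_yaml(side)
  rows <- tibble::as_tibble(utils::read.csv(gzfile(path)))
  cnt <- unlist(meta$first_channel_counts)
  # reconstruct a per-history tag vector consistent with the stored counts
  fc <- rep.int(0:3, cnt)
  structure(list(
    n_primaries = meta$n_primaries,
    first_channel = fc,
    pairs = dplyr::select(dplyr::filter(rows, .data$type == "pair"),
                          -"type") |>
      dplyr::select(dplyr::where(~ !all(is.na(.x)))),
    annihilations = dplyr::select(dplyr::filter(rows,
                                                .data$type == "annihilation"),
                                  -"type") |>
      dplyr::select(dplyr::where(~ !all(is.na(.x)))),
    photons = dplyr::select(dplyr::filter(rows, .data$type == "photon"),
                            -"type") |>
      dplyr::select(dplyr::where(~ !all(is.na(.x)))),
    config = do.call(ppt_config, meta$config),
    seed = meta$seed,
    grid_shape = unlist(meta$grid_shape),
    voxel_mm = unlist(meta$voxel_mm)), class = "ppt_eventlog")
}
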