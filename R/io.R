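# Delimited-text readers and writers for the three tabular stages. All
# files are plain TSV with a header; the ITC format carries its metadata
# (cell volume, concentrations, temperature) in '#'-prefixed key: value
# lines above the header.

#' Read and write thioflavin-T curve files
#'
#' Long-format TSV with columns `time`, `value`, `replicate`, `label`.
#'
#' @param path File path.
#' @param data Tibble as produced by [gen_tht()].
#' @return `read_tht()` returns the tibble; `write_tht()` returns `path`
#'   invisibly.
#' @export
read_tht <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time", "value", "replicate", "label")
  if (!all(need %in% names(d))) {
    stop("ThT file needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' @rdname read_tht
#' @export
write_tht <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}

#' Read and write plasma concentration files
#'
#' Long-format TSV with columns `time_h`, `concentration`, `subject`,
#' `group`.
#'
#' @param path File path.
#' @param data Tibble as produced by [gen_pk()].
#' @return `read_pk()` returns the tibble; `write_pk()` returns `path`
#'   invisibly.
#' @export
read_pk <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_h", "concentration", "subject", "group")
  if (!all(need %in% names(d))) {
    stop("PK file needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' @rdname read_pk
#' @export
write_pk <- function(data, path) {
  readr::write_tsv(data, path, progress = FALSE)
  invisible(path)
}

#' Read and write ITC thermogram files
#'
#' TSV with columns `injection`, `volume_uL`, `heat_ucal`, preceded by a
#' metadata block of `# key: value` lines describing the titration geometry
#' (`cell_volume_uL`, `syringe_conc_uM`, `cell_conc_uM`, `temperature_K`).
#'
#' @param path File path.
#' @param data Tibble as produced by [gen_itc()].
#' @param geometry An [itc_geometry()]; defaults to the geometry attribute
#'   attached by [gen_itc()].
#' @return `read_itc()` returns the data tibble with the parsed geometry in
#'   attribute `"geometry"`; `write_itc()` returns `path` invisibly.
#' @export
read_itc <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- as.numeric(kv[2])
  }
  d <- readr::read_tsv(I(grep("^#", lines, value = TRUE, invert = TRUE)),
                       show_col_types = FALSE, progress = FALSE)
  need <- c("injection", "volume_uL", "heat_ucal")
  if (!all(need %in% names(d))) {
    stop("ITC file needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  needed_meta <- c("cell_volume_uL", "syringe_conc_uM", "cell_conc_uM",
                   "temperature_K")
  if (!all(needed_meta %in% names(meta))) {
    stop("ITC file needs metadata lines for ",
         paste(needed_meta, collapse = ", "), call. = FALSE)
  }
  attr(d, "geometry") <- itc_geometry(
    cell_volume_uL = meta$cell_volume_uL,
    syringe_conc_uM = meta$syringe_conc_uM,
    cell_conc_uM = meta$cell_conc_uM,
    injection_volumes_uL = d$volume_uL,
    temperature_K = meta$temperature_K
  )
  d
}

#' @rdname read_itc
#' @export
write_itc <- function(data, path, geometry = attr(data, "geometry")) {
  stopifnot(inherits(geometry, "itc_geometry"))
  hdr <- sprintf("# %s: %.10g",
                 c("cell_volume_uL", "syringe_conc_uM", "cell_conc_uM",
                   "temperature_K"),
                 c(geometry$cell_volume_uL, geometry$syringe_conc_uM,
                   geometry$cell_conc_uM, geometry$temperature_K))
  readr::write_lines(hdr, path)
  readr::write_tsv(data[, c("injection", "volume_uL", "heat_ucal")], path,
                   append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
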