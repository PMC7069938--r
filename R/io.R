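#' Write / read an RF record as a self-describing text container
#'
#' Single-file plain-text container: the first line is a `#sparsus-rf`
#' comment carrying a JSON header (sampling rate, time origin, modality,
#' geometry provenance), followed by the tab-separated time x element
#' sample matrix.
#'
#' @param rf A `sparsus_rf` object.
#' @param path Output file path.
#' @return `write_rf()`: the path, invisibly. `read_rf()`: a `sparsus_rf`.
#' @export
write_rf <- function(rf, path) {
  header <- list(
    container = "sparsus-rf",
    sampling_rate_hz = rf$fs,
    t0_s = rf$t0,
    modality = rf$modality,
    n_samples = nrow(rf$samples),
    n_elements = ncol(rf$samples),
    probe = list(n_elements = rf$probe$n_elements, pitch_m = rf$probe$pitch,
                 center_x_m = mean(range(rf$probe$element_x))),
    subset_indices = rf$subset$indices,
    subset_scheme = rf$subset$scheme
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#sparsus-rf ", jsonlite::toJSON(header, auto_unbox = TRUE,
                                                     digits = NA)), con)
  utils::write.table(rf$samples, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_rf
#' @export
read_rf <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#sparsus-rf ")) {
    rlang::abort("Not a sparsus RF container (missing '#sparsus-rf' header).",
                 class = "sparsus_error_io")
  }
  h <- jsonlite::fromJSON(sub("^#sparsus-rf ", "", first))
  samples <- as.matrix(utils::read.table(path, sep = "\t", skip = 1))
  dimnames(samples) <- NULL
  probe <- make_linear_probe(h$probe$n_elements, h$probe$pitch_m,
                             h$probe$center_x_m)
  structure(
    list(samples = samples, fs = h$sampling_rate_hz, t0 = h$t0_s,
         modality = h$modality, probe = probe,
         subset = structure(list(indices = as.integer(h$subset_indices),
                                 scheme = h$subset_scheme,
                                 n_total = probe$n_elements),
                            class = "sparsus_subset")),
    class = "sparsus_rf"
  )
}

#' Write a 2D image matrix as a text container
#'
#' @param img Numeric matrix (rows = depth).
#' @param path Output file path.
#' @param meta Named list of scalar metadata merged into the JSON header.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path, meta = list()) {
  header <- c(list(container = "sparsus-image",
                   n_z = nrow(img), n_x = ncol(img)), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#sparsus-image ", jsonlite::toJSON(header, auto_unbox = TRUE,
                                                        digits = NA)), con)
  utils::write.table(img, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_image
#' @return `read_image()`: a list with `img` and `meta`.
#' @export
read_image <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#sparsus-image ")) {
    rlang::abort("Not a sparsus image container.", class = "sparsus_error_io")
  }
  meta <- jsonlite::fromJSON(sub("^#sparsus-image ", "", first))
  img <- as.matrix(utils::read.table(path, sep = "\t", skip = 1))
  dimnames(img) <- NULL
  list(img = img, meta = meta)
}
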