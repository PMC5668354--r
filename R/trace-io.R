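#' Read and write force-trace TSV files
#'
#' The on-disk dialect is a tab-separated table with a single comment header
#' line holding the acquisition metadata, e.g.
#' `# k_N_per_m=0.3 sensitivity_m_per_V=5e-08 h_set_um=14 wedged=FALSE`,
#' followed by columns `t_s` and `F_N` (or `t_s` and `Vd_V` for raw
#' photodiode traces).
#'
#' @param path File path.
#' @param trace A [force_trace()] to write.
#' @param h_set_um Preset cantilever height recorded in the header.
#' @return `read_force_trace()` returns a [force_trace()] with the cantilever
#'   spec attached and the header height in attribute `h_set_um`;
#'   `write_force_trace()` returns `path` invisibly.
#' @name trace_io
NULL

#' @rdname trace_io
#' @export
read_force_trace <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) {
    abort("missing metadata header line.", class = "mitomech_data_error")
  }
  kv <- strsplit(trimws(sub("^#\\s*", "", header)), "\\s+")[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  meta <- setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  spec <- cantilever_spec(
    k = as.numeric(meta$k_N_per_m %||% 0.3),
    wedged = isTRUE(as.logical(meta$wedged %||% "FALSE")),
    deflection_sensitivity = if (!is.null(meta$sensitivity_m_per_V))
      as.numeric(meta$sensitivity_m_per_V)
  )
  dat <- utils::read.delim(path, comment.char = "#", header = TRUE)
  tr <- if ("F_N" %in% names(dat)) {
    force_trace(dat$t_s, F_N = dat$F_N, spec = spec)
  } else if ("Vd_V" %in% names(dat)) {
    force_trace(dat$t_s, Vd_V = dat$Vd_V, spec = spec)
  } else {
    abort("expected columns t_s and F_N (or Vd_V).",
          class = "mitomech_data_error")
  }
  attr(tr, "h_set_um") <- as.numeric(meta$h_set_um %||% NA_real_)
  tr
}

#' @rdname trace_io
#' @export
write_force_trace <- function(trace, path, h_set_um = NA_real_) {
  stopifnot(inherits(trace, "force_trace"))
  spec <- attr(trace, "spec") %||% cantilever_spec()
  header <- sprintf("# k_N_per_m=%.6g%s h_set_um=%g wedged=%s",
                    spec$k,
                    if (!is.null(spec$deflection_sensitivity))
                      sprintf(" sensitivity_m_per_V=%.6g",
                              spec$deflection_sensitivity) else "",
                    h_set_um, spec$wedged)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(as.data.frame(trace)[, intersect(c("t_s", "F_N", "Vd_V"),
                                                      names(trace))],
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write event-annotation tables
#'
#' Annotations are stored as CSV with columns `cell_id,event,t_s`.
#'
#' @param path File path.
#' @param annotations A data frame with columns `cell_id`, `event`, `t_s`.
#' @return `read_annotations()` returns a tibble; use
#'   [annotations_for_cell()] to extract one cell's named event vector.
#' @name annotation_io
NULL

#' @rdname annotation_io
#' @export
read_annotations <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    cell_id = readr::col_character(),
    event = readr::col_character(),
    t_s = readr::col_double()
  ))
}

#' @rdname annotation_io
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(as_tibble(annotations)[, c("cell_id", "event", "t_s")], path)
  invisible(path)
}

#' @param cell_id Cell identifier to extract.
#' @rdname annotation_io
#' @export
annotations_for_cell <- function(annotations, cell_id) {
  rows <- annotations[annotations$cell_id == cell_id, ]
  setNames(rows$t_s, rows$event)
}
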