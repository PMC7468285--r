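#' Curve-set container and delimited-text I/O
#'
#' A curve set is a plain data frame holding a family of
#' concentration-response curves, one per fixed allosteric-ligand
#' concentration, with columns \code{curve_id}, \code{modulator_conc_M},
#' \code{agonist_conc_M}, \code{response} and optionally \code{sd} and
#' \code{replicate}.  \code{as_curveset()} validates the layout (at least
#' one curve, at least 4 distinct agonist concentrations per curve,
#' non-negative molar concentrations) and stamps the class
#' \code{"curveset"}.
#'
#' @param x a data frame with the columns above
#' @return a validated \code{curveset} data frame
#' @examples
#' df <- data.frame(curve_id = "c1", modulator_conc_M = 0,
#'                  agonist_conc_M = c(0, 1e-8, 1e-7, 1e-6, 1e-5),
#'                  response = c(0, .1, .3, .6, .72))
#' cs <- as_curveset(df)
#' @export
as_curveset <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("curve_id", "modulator_conc_M", "agonist_conc_M", "response")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (cl in c("modulator_conc_M", "agonist_conc_M", "response")) {
    bad <- which(!is.finite(x[[cl]]))
    if (length(bad))
      stop(sprintf("non-numeric or non-finite value in column '%s' at row %d",
                   cl, bad[1]), call. = FALSE)
  }
  for (cl in c("modulator_conc_M", "agonist_conc_M")) {
    bad <- which(x[[cl]] < 0)
    if (length(bad))
      stop(sprintf("negative concentration in column '%s' at row %d",
                   cl, bad[1]), call. = FALSE)
  }
  n_per <- tapply(x$agonist_conc_M, x$curve_id,
                  function(a) length(unique(a)))
  if (any(n_per < 4L))
    stop("each curve needs at least 4 distinct agonist concentrations",
         call. = FALSE)
  class(x) <- unique(c("curveset", class(x)))
  x
}

#' @rdname as_curveset
#' @param path file path; a \code{.tsv}/\code{.txt} extension selects
#'   tab-delimited format, anything else comma-delimited
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_curveset(df)
}

#' @rdname as_curveset
#' @param curves a \code{curveset} data frame
#' @export
write_curves <- function(curves, path) {
  curves <- as_curveset(as.data.frame(curves))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(curves, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and write radioligand-binding tables
#'
#' Binding tables are delimited text with columns \code{ligand_conc_M}
#' (titrated ligand, molar) and \code{binding_pct} (specific binding as per
#' cent of control, or raw counts for saturation data), plus optional
#' \code{replicate} and \code{agonist_conc_M} (for designs with a fixed
#' orthosteric agonist).
#'
#' @param path file path (.tsv/.txt tab-delimited, otherwise CSV)
#' @return a validated data frame
#' @export
read_binding <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("ligand_conc_M", "binding_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$ligand_conc_M) | df$ligand_conc_M < 0)
  if (length(bad))
    stop(sprintf("invalid concentration at row %d", bad[1]), call. = FALSE)
  df
}

#' @rdname read_binding
#' @param binding a binding-table data frame
#' @export
write_binding <- function(binding, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(binding, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key-value configuration for the command-line interface and the
#' staged workflow: predetermined parameter values (\code{e_max},
#' \code{basal}, \code{k_a}, \code{tau_a}, \code{k_b}, \code{tau_b}),
#' \code{k_b_source} (\code{"binding"} or \code{"functional"}),
#' \code{saturation_p}, \code{fix_n_h}, \code{seed}.
#'
#' @param path path to a YAML file
#' @return a named list
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("e_max", "basal", "k_a", "tau_a", "k_b", "tau_b",
             "k_b_source", "saturation_p", "fix_n_h", "seed", "weights")
  # YAML 1.1 reads exponent notation without a decimal point ("1e-6") as a
  # string; coerce the numeric keys back
  numeric_keys <- c("e_max", "basal", "k_a", "tau_a", "k_b", "tau_b",
                    "saturation_p", "fix_n_h", "seed")
  for (k in intersect(names(cfg), numeric_keys)) {
    if (is.character(cfg[[k]])) {
      v <- suppressWarnings(as.numeric(cfg[[k]]))
      if (anyNA(v))
        stop(sprintf("config key '%s' is not numeric: %s", k, cfg[[k]]),
             call. = FALSE)
      cfg[[k]] <- v
    } else if (is.list(cfg[[k]])) {
      cfg[[k]] <- vapply(cfg[[k]], function(z)
        suppressWarnings(as.numeric(z)), 0)
    }
  }
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  cfg
}

# split a curveset into per-curve data frames, ordered by modulator conc
split_curves <- function(curves) {
  curves <- as_curveset(as.data.frame(curves))
  parts <- split(curves, curves$curve_id)
  ord <- order(vapply(parts, function(d) d$modulator_conc_M[1], 0))
  parts[ord]
}
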