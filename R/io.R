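#' Read a table of difference scores
#'
#' Reads delimited text (TSV or CSV, sniffed from the header line) with a
#' header and at least a score column, or a BED-style interval file whose
#' score column supplies `y` (coordinates are carried through untouched;
#' no coordinate arithmetic is performed, so base convention is
#' irrelevant). Rows with missing scores are dropped with a message. When
#' an intensity column is present, robustness weights are attached via
#' [compute_weights()]; otherwise all weights are 1.
#'
#' @param path File path.
#' @param format `"auto"`, `"table"`, or `"bed"`. `"auto"` treats files
#'   ending in `.bed` as BED and everything else as a delimited table.
#' @param id_col,y_col,u_col Column names in table format; `u_col` is
#'   optional in the file.
#' @param weight_fun,tail,c,taper Weighting options, as in
#'   [compute_weights()].
#' @return Tibble with columns `id`, `y`, `w` (and `u` plus any BED
#'   coordinate columns when present).
#' @export
read_scores <- function(path, format = c("auto", "table", "bed"),
                        id_col = "id", y_col = "y", u_col = "u",
                        weight_fun = "huber", tail = "lower",
                        c = 1.345, taper = 4.685) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "table"
  }
  if (format == "bed") {
    raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           comment = "#")
    if (ncol(raw) < 5) abort("BED input needs at least 5 columns (score in column 5).")
    names(raw)[1:5] <- c("chrom", "start", "end", "id", "score")
    raw$y <- suppressWarnings(as.numeric(raw$score))
    tab <- raw
  } else {
    header <- readLines(path, n = 1)
    if (length(header) == 0) abort("input file is empty.")
    delim <- if (grepl("\t", header)) "\t" else ","
    tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
    if (!y_col %in% names(tab)) {
      abort(sprintf("score column `%s` not found in %s", y_col, path))
    }
    yraw <- tab[[y_col]]
    if (!is.numeric(yraw)) {
      bad <- which(is.na(suppressWarnings(as.numeric(yraw))) & !is.na(yraw))
      if (length(bad) > 0) {
        abort(sprintf("non-numeric score in row %d of %s", bad[1], path))
      }
      yraw <- as.numeric(yraw)
    }
    tab$y <- yraw
    if (id_col %in% names(tab)) tab$id <- tab[[id_col]]
    if (u_col %in% names(tab) && u_col != "u") tab$u <- tab[[u_col]]
  }
  n0 <- nrow(tab)
  tab <- tab[!is.na(tab$y), ]
  if (nrow(tab) < n0) {
    message(sprintf("dropped %d row(s) with missing scores", n0 - nrow(tab)))
  }
  if (nrow(tab) == 0) abort("no usable rows in input.")
  if (!"id" %in% names(tab)) tab$id <- seq_len(nrow(tab))
  compute_weights(tab, weight_fun = weight_fun, tail = tail, c = c,
                  taper = taper)
}

#' Write per-unit classification and replicate-study tables
#'
#' Plain TSV writers (12 significant digits, so a write/read round trip
#' reproduces the numbers exactly at double precision for these scales).
#'
#' @param x The table to write: a classification tibble (from
#'   [augment()] on an ensemble fit), a replicate-study tibble, or a
#'   simulated dataset.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_result <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.numeric),
    ~ ifelse(. == round(.), ., signif(., 12))
  ))
  readr::write_tsv(x, path)
  invisible(path)
}

#' QQ table of data quantiles against fitted-model quantiles
#'
#' Computes matched quantiles of the observed scores and of the fitted
#' mixture (model quantiles by numerical inversion of the CDF obtained
#' from quadrature on a fine grid). A straight diagonal indicates good
#' fit.
#'
#' @param fit A `mix_fit` or `mix_ensemble` (its winner is used).
#' @param data Data frame with `y`; defaults to the data stored in an
#'   ensemble fit.
#' @param n_points Number of quantile points; default 200.
#' @return Tibble with `prob`, `data_quantile`, `model_quantile`.
#' @export
qq_table <- function(fit, data = NULL, n_points = 200) {
  if (inherits(fit, "mix_ensemble")) {
    data <- data %||% fit$data
    fit <- fit$best
  }
  stopifnot(inherits(fit, "mix_fit"))
  data <- as_fit_data(data)
  y <- data$y
  probs <- (seq_len(n_points) - 0.5) / n_points
  lo <- min(y) - 4 * sd(y); hi <- max(y) + 4 * sd(y)
  grid <- seq(lo, hi, length.out = 4096)
  dens <- mixture_density(fit$model, grid)
  cdf <- cumsum(dens) * (grid[2] - grid[1])
  cdf <- cdf / cdf[length(cdf)]
  model_q <- approx(cdf, grid, xout = probs, ties = "ordered", rule = 2)$y
  tibble::tibble(prob = probs,
                 data_quantile = as.numeric(quantile(y, probs, type = 7)),
                 model_quantile = model_q)
}
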