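## Morphogen parameter tables and figure-style datasets.

.EVIDENCE_CLASSES <- c("DT", "SDC", "multiple")

.validate_morphogen_records <- function(df) {
  required <- c("name", "species", "lambda_um", "a_um", "N", "evidence_class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  probs <- character(0)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    bad <- c(
      if (!is.finite(row$lambda_um) || row$lambda_um <= 0)
        "lambda_um must be positive",
      if (!is.finite(row$a_um) || row$a_um <= 0) "a_um must be positive",
      if (!is.finite(row$N) || row$N < 3 || row$N != round(row$N))
        "N must be an integer >= 3",
      if (!row$evidence_class %in% .EVIDENCE_CLASSES)
        sprintf("unknown evidence_class '%s'", row$evidence_class))
    if (length(bad))
      probs <- c(probs, sprintf("row %d (%s): %s", i, row$name,
                                paste(bad, collapse = "; ")))
  }
  if (length(probs))
    stop("invalid morphogen record(s):\n  ", paste(probs, collapse = "\n  "))
  if (anyDuplicated(df$name))
    stop("morphogen names must be unique")
  df$N <- as.integer(df$N)
  df
}

#' Load a morphogen parameter table
#'
#' Reads a CSV with columns `name`, `species`, `lambda_um` (profile
#' lengthscale, micrometres), `a_um` (cell radius, micrometres), `N`
#' (target cells per side) and `evidence_class` (one of `"DT"`, `"SDC"`,
#' `"multiple"`); an optional `provenance_note` column documents where
#' each row's values come from. Malformed rows are rejected with
#' row-numbered messages. The derived dimensionless lengthscale
#' \eqn{\hat\lambda = \lambda/a} is added.
#'
#' A template with ten commonly studied morphogens ships at
#' `system.file("extdata", "morphogens_synthetic.csv", package =
#' "morphosense")`; its numeric values are synthetic order-of-magnitude
#' placeholders (flagged `unverified` in `provenance_note`) meant to
#' exercise the pipeline, and must be replaced with literature estimates
#' before any biological conclusion is drawn.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame with derived `lambda_hat`.
#' @export
load_morphogen_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df <- .validate_morphogen_records(df)
  df$lambda_hat <- df$lambda_um / df$a_um
  df
}

#' Figure-style datasets
#'
#' Regenerates, as deterministic data frames, the three dataset kinds
#' behind the package's standard figures:
#' \describe{
#'   \item{`"fig3a"`}{DT precision \eqn{P^2_j(\phi)} over a log grid of
#'     \eqn{\phi} for several lengthscales at fixed `N`, `j`
#'     (\eqn{\beta = T = \nu = 1}); each curve has an interior maximum
#'     \eqn{\phi^*}.}
#'   \item{`"fig3b"`}{the precision ratio \eqn{\rho_j} against
#'     \eqn{\hat\lambda} for the requested dimensionalities; crosses 1
#'     once, from DT-favoured to SDC-favoured.}
#'   \item{`"fig4b"`}{per-morphogen \eqn{\hat\lambda/\hat\lambda_{50}}
#'     with the fraction of cells favouring SDC, plus the lengthscales at
#'     which that fraction reaches the standard 25/50/75% contour
#'     levels for each distinct `N`.}
#' }
#'
#' @param kind One of `"fig3a"`, `"fig3b"`, `"fig4b"`.
#' @param N Cells per side (fig3a/fig3b; default 100).
#' @param j Probed cell (fig3a/fig3b; default `N/2`).
#' @param lambda_hat_values Lengthscales for fig3a curves.
#' @param lambda_grid Lengthscale grid for fig3b.
#' @param dims Dimensionalities for fig3b (default 1).
#' @param phi_grid phi grid for fig3a.
#' @param records Morphogen table for fig4b (see
#'   [load_morphogen_table()]).
#' @return A data frame (fig4b: list of `records` and `contours` data
#'   frames).
#' @export
figure_data <- function(kind = c("fig3a", "fig3b", "fig4b"), N = 100,
                        j = NULL,
                        lambda_hat_values = c(1, 2, 5, 10, 20),
                        lambda_grid = exp(seq(log(1), log(200),
                                              length.out = 13)),
                        dims = 1L,
                        phi_grid = exp(seq(log(1e-3), log(30),
                                           length.out = 200)),
                        records = NULL) {
  kind <- match.arg(kind)
  if (is.null(j)) j <- N %/% 2
  if (kind == "fig3a") {
    out <- do.call(rbind, lapply(lambda_hat_values, function(lh) {
      p2 <- as.numeric(.dt_p2_matrix(N, lh, phi_grid, j))
      data.frame(lambda_hat = lh, phi = phi_grid, p_squared = p2)
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (kind == "fig3b") {
    out <- do.call(rbind, lapply(dims, function(d) {
      do.call(rbind, lapply(lambda_grid, function(lh) {
        cr <- precision_ratio(N, lh, dim = d, j = j)
        data.frame(dim = d, lambda_hat = lh, rho = cr$rho,
                   phi_star = cr$phi_star)
      }))
    }))
    rownames(out) <- NULL
    return(out)
  }
  ## fig4b
  if (is.null(records))
    records <- load_morphogen_table(
      system.file("extdata", "morphogens_synthetic.csv",
                  package = "morphosense"))
  cl <- classify_morphogens(records)
  recs <- cl$records[order(cl$records$lambda_hat_over_lambda50), ]
  contours <- do.call(rbind, lapply(unique(recs$N), function(n) {
    lev <- c(0.25, 0.5, 0.75)
    data.frame(N = n, level = lev,
               lambda_hat = vapply(lev, function(q)
                 .lambda_at_fraction(n, q), numeric(1)))
  }))
  list(records = recs, contours = contours)
}
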