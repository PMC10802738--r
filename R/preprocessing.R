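#' Box-Cox transform a vector of positive measurements
#'
#' Applies the power transform `(x^lambda - 1)/lambda` (natural log at
#' `lambda = 0`). When `lambda = "estimate"`, lambda maximizes the Box-Cox
#' profile log-likelihood over a fixed grid, with ties broken toward 0 so that
#' near-lognormal aptamers land on the interpretable log scale.
#'
#' @param x positive numeric vector (after `shift`).
#' @param lambda a number, or `"estimate"`.
#' @param shift non-negative constant added to `x` before transforming, for
#'   assays reporting non-positive values.
#' @param grid candidate lambdas used when estimating (default
#'   `seq(-2, 2, by = 0.01)`).
#' @param name label used in error messages (e.g. the aptamer id).
#' @return list with `values` (transformed vector, NAs preserved) and
#'   `lambda` (the lambda used).
#' @export
boxcox_transform <- function(x, lambda = "estimate", shift = 0,
                             grid = seq(-2, 2, by = 0.01), name = "x") {
  stopifnot(is.numeric(x), shift >= 0)
  x <- x + shift
  ok <- !is.na(x)
  if (any(x[ok] <= 0))
    stop(sprintf("non-positive values in '%s' (supply a shift)", name),
         call. = FALSE)
  bc <- function(v, l) if (abs(l) < 1e-12) log(v) else (v^l - 1) / l
  if (identical(lambda, "estimate")) {
    v <- x[ok]
    n <- length(v)
    slog <- sum(log(v))
    ll <- vapply(grid, function(l) {
      y <- bc(v, l)
      -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slog
    }, numeric(1))
    best <- which(ll > max(ll) - 1e-9)
    lambda <- grid[best[which.min(abs(grid[best]))]]  # tie -> closest to 0
  }
  stopifnot(is.numeric(lambda), length(lambda) == 1L)
  out <- rep(NA_real_, length(x))
  out[ok] <- bc(x[ok], lambda)
  list(values = out, lambda = lambda)
}

#' Standardize a protein matrix and mask extreme outliers
#'
#' Per aptamer (column): optional shift for non-positive values, Box-Cox
#' transform, centering and scaling to mean 0 / SD 1 (moments computed before
#' any masking), then entries with `|z| > outlier_sd` set to `NA`. Zero- or
#' near-zero-variance columns are dropped with a warning and listed in the
#' report. Missingness is propagated as-is: downstream association fits are
#' complete-case per aptamer.
#'
#' @param mat numeric matrix, samples x aptamers (column names = aptamer ids).
#' @param lambda per-column lambda(s), or `"estimate"` (the default).
#' @param outlier_sd outlier threshold in SD units (> 0; default 4).
#' @param shift per-column non-negative shifts, or `"auto"` to shift any
#'   column with non-positive values to a minimum of 1.
#' @return list of class `preprocessed_matrix`:
#'   \item{matrix}{transformed, standardized matrix with outliers `NA`.}
#'   \item{params}{data.frame `aptamer`, `lambda`, `shift`, `n_excluded`.}
#'   \item{dropped}{character vector of dropped (degenerate) aptamers.}
#' @export
standardize_and_filter <- function(mat, lambda = "estimate", outlier_sd = 4,
                                   shift = "auto") {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (!is.numeric(outlier_sd) || outlier_sd <= 0)
    stop("outlier_sd must be > 0", call. = FALSE)
  ids <- colnames(mat)
  if (is.null(ids)) ids <- sprintf("apt_%d", seq_len(ncol(mat)))
  lambdas <- if (identical(lambda, "estimate")) rep(list("estimate"), ncol(mat))
             else as.list(rep_len(lambda, ncol(mat)))
  auto_shift <- identical(shift, "auto")
  shifts <- if (auto_shift) numeric(ncol(mat)) else rep_len(shift, ncol(mat))

  out <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = list(rownames(mat), ids))
  params <- data.frame(aptamer = ids, lambda = NA_real_, shift = 0,
                       n_excluded = 0L, stringsAsFactors = FALSE)
  dropped <- character(0)
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    if (stats::sd(x, na.rm = TRUE) < 1e-12 || all(is.na(x))) {
      dropped <- c(dropped, ids[j])
      next
    }
    s <- if (auto_shift && min(x, na.rm = TRUE) <= 0)
      1 - min(x, na.rm = TRUE) else shifts[j]
    tr <- boxcox_transform(x, lambda = lambdas[[j]], shift = s, name = ids[j])
    y <- tr$values
    z <- (y - mean(y, na.rm = TRUE)) / stats::sd(y, na.rm = TRUE)
    mask <- !is.na(z) & abs(z) > outlier_sd
    z[mask] <- NA_real_
    out[, j] <- z
    params$lambda[j] <- tr$lambda
    params$shift[j] <- s
    params$n_excluded[j] <- sum(mask)
  }
  if (length(dropped)) {
    warning(sprintf("dropped %d zero-variance aptamer(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
    out <- out[, setdiff(ids, dropped), drop = FALSE]
    params <- params[params$aptamer %in% colnames(out), , drop = FALSE]
  }
  structure(list(matrix = out, params = params, dropped = dropped),
            class = "preprocessed_matrix")
}

#' @export
print.preprocessed_matrix <- function(x, ...) {
  cat(sprintf("<preprocessed_matrix> %d samples x %d aptamers; %d outliers masked; %d dropped\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$params$n_excluded),
              length(x$dropped)))
  invisible(x)
}

#' Read / write a protein matrix TSV (samples x aptamers, first column = id)
#'
#' @param path file path.
#' @return numeric matrix with sample row names.
#' @export
read_protein_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
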