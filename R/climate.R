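#' Dendrochronological month window
#'
#' The month range over which monthly climate is correlated with growth.
#' The default — previous-year June through current-year September — is the
#' classic 16-month window for a northern-hemisphere growth year; months of
#' the previous calendar year are labelled `pJun..pDec`.
#'
#' @param start_month,start_lag First month (1-12) and its year lag
#'   (`-1` = previous calendar year). Default June, lag -1.
#' @param end_month,end_lag Last month and lag. Default September, lag 0.
#' @return An object of class `dendro_window` with one row per month:
#'   `lag`, `month`, `label`.
#' @export
dendro_window <- function(start_month = 6L, start_lag = -1L,
                          end_month = 9L, end_lag = 0L) {
  if (!start_lag %in% c(-1L, 0L) || !end_lag %in% c(-1L, 0L))
    stop("lags must be -1 (previous year) or 0 (current year)")
  s <- start_lag * 12L + start_month
  e <- end_lag * 12L + end_month
  if (s > e) stop("window start must precede its end in dendro ordering")
  lin <- seq.int(s, e)
  lag <- ifelse(lin <= 0L, -1L, 0L)
  mon <- ifelse(lin <= 0L, lin + 12L, lin)
  lab <- ifelse(lag == -1L, paste0("p", month.abb[mon]), month.abb[mon])
  structure(data.frame(lag = lag, month = mon, label = lab),
            class = c("dendro_window", "data.frame"))
}

#' Align a chronology with monthly climate over a window
#'
#' Builds the year-aligned design matrix: one column per (variable, window
#' month), one row per response year `t` for which the chronology index and
#' every window month are non-missing. Previous-year months are taken from
#' calendar year `t - 1`.
#'
#' @param chronology A [build_chronology()] result (prewhitened indices
#'   recommended for correlation work).
#' @param climate A [climate_table] or a list of them.
#' @param window A [dendro_window].
#' @param min_overlap Minimum number of complete response years (default 30).
#' @return List with `years`, `index` (chronology values) and `design`
#'   (matrix with columns `<variable>.<label>`).
#' @export
align_climate <- function(chronology, climate, window = dendro_window(),
                          min_overlap = 30L) {
  stopifnot(inherits(chronology, "chronology"))
  if (inherits(climate, "climate_table")) climate <- list(climate)
  yrs <- chronology$years[is.finite(chronology$index)]
  cols <- list()
  for (ct in climate) {
    stopifnot(inherits(ct, "climate_table"))
    for (k in seq_len(nrow(window))) {
      src_year <- yrs + window$lag[k]
      v <- rep(NA_real_, length(yrs))
      m <- match(src_year, ct$years)
      ok <- !is.na(m)
      v[ok] <- ct$values[cbind(m[ok], window$month[k])]
      cols[[paste0(ct$variable, ".", window$label[k])]] <- v
    }
  }
  design <- do.call(cbind, cols)
  idx <- chronology$index[match(yrs, chronology$years)]
  complete <- rowSums(is.na(design)) == 0L & is.finite(idx)
  if (sum(complete) < min_overlap)
    stop("chronology/climate overlap too short: ", sum(complete),
         " complete years (< ", min_overlap, ")")
  list(years = yrs[complete], index = idx[complete],
       design = design[complete, , drop = FALSE])
}

# bootstrap correlations of y with every column of X for one shared set of
# case resamples; returns sample r plus the n_boot x p bootstrap r matrix
.boot_cor <- function(y, X, idx_mat) {
  n <- length(y); B <- nrow(idx_mat)
  r_hat <- suppressWarnings(as.numeric(stats::cor(y, X)))
  iv <- as.vector(t(idx_mat))                    # column-major resample index
  Yb <- matrix(y[iv], nrow = n)                  # n x B resampled responses
  sy <- colSums(Yb); syy <- colSums(Yb^2)
  rb <- matrix(NA_real_, B, ncol(X))
  for (j in seq_len(ncol(X))) {
    Xb <- matrix(X[iv, j], nrow = n)
    sx <- colSums(Xb); sxx <- colSums(Xb^2)
    sxy <- colSums(Yb * Xb)
    num <- sxy - sx * sy / n
    den <- sqrt(pmax(sxx - sx^2 / n, 0) * pmax(syy - sy^2 / n, 0))
    rb[, j] <- ifelse(den > 0, num / den, NA_real_)
  }
  list(r = r_hat, boot = rb)
}

#' Bootstrap correlation function between growth and monthly climate
#'
#' Pearson correlation of the chronology with each (variable, month) column
#' over the dendro window, with case-bootstrap (years resampled with
#' replacement) percentile confidence intervals. A month is significant
#' when its CI excludes zero. Deterministic given `seed`.
#'
#' @param chronology,climate,window,min_overlap Passed to [align_climate].
#' @param n_boot Number of bootstrap replicates (>= 100, default 1000).
#' @param alpha Two-sided level (default 0.05, i.e. 95% CIs).
#' @param seed Integer seed; the global RNG state is restored afterwards.
#' @param bonferroni Divide `alpha` by the number of months tested
#'   (off by default, matching per-month significance stars).
#' @return A data.frame with class `response_result`: `variable`, `month`,
#'   `r`, `ci_low`, `ci_high`, `significant`, `n_years`, `n_boot`.
#' @export
bootstrap_correlation <- function(chronology, climate,
                                  window = dendro_window(),
                                  n_boot = 1000L, alpha = 0.05,
                                  seed = NULL, bonferroni = FALSE,
                                  min_overlap = 30L) {
  if (n_boot < 100L) stop("n_boot must be >= 100")
  al <- align_climate(chronology, climate, window, min_overlap)
  n <- length(al$years)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  idx_mat <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  bc <- .boot_cor(al$index, al$design, idx_mat)
  a <- if (bonferroni) alpha / ncol(al$design) else alpha
  cn <- strsplit(colnames(al$design), ".", fixed = TRUE)
  out <- data.frame(
    variable = vapply(cn, `[`, character(1), 1L),
    month = vapply(cn, `[`, character(1), 2L),
    r = bc$r, ci_low = NA_real_, ci_high = NA_real_,
    significant = FALSE, n_years = n, n_boot = as.integer(n_boot),
    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(al$design))) {
    if (!is.finite(bc$r[j])) next   # zero-variance column: flagged, not significant
    q <- stats::quantile(bc$boot[, j], c(a / 2, 1 - a / 2), na.rm = TRUE,
                         names = FALSE)
    out$ci_low[j] <- q[1L]; out$ci_high[j] <- q[2L]
    out$significant[j] <- q[1L] > 0 || q[2L] < 0
  }
  attr(out, "seed") <- seed
  attr(out, "alpha") <- alpha
  class(out) <- c("response_result", "data.frame")
  out
}

#' Write a climate-response CSV
#' @param response A [bootstrap_correlation()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(response, path) {
  utils::write.csv(as.data.frame(response), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
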