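hrv_factor_vars <- c("rmssd", "sdnn", "pnni_50", "total_power",
                     "hf_power_norm", "cvi", "csi")

#' Assemble the factor-analysis input from normalized windows
#'
#' Selects the seven autonomic indices (RMSSD, SDNN, pNNI-50, total
#' power, normalized HF power, CVI, CSI) in their daily-z form from a
#' [normalize_daily()] table. Each sliding window is one observation,
#' standardized by its own subject-day reference, so between-subject and
#' between-day level differences are removed before the correlation
#' structure is analysed. Rows with any missing value are dropped and
#' counted.
#'
#' @param windows Output of [normalize_daily()].
#' @return A tibble with the seven variables; the number of dropped
#'   rows is in attribute `n_dropped`.
#' @export
factor_input <- function(windows) {
  zcols <- paste0("z_", hrv_factor_vars)
  missing <- setdiff(zcols, names(windows))
  if (length(missing) > 0) {
    abort(paste0("`windows` lacks normalized columns: ",
                 paste(missing, collapse = ", ")))
  }
  x <- windows[, zcols]
  names(x) <- hrv_factor_vars
  ok <- complete.cases(x)
  out <- x[ok, ]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Bartlett's test of sphericity
#'
#' Tests whether the correlation matrix of the input differs from the
#' identity — the gate for whether factor analysis is meaningful.
#'
#' @param data A numeric data frame (observations x variables).
#' @return A one-row tibble: `chisq`, `df`, `p_value`, `n`.
#' @export
bartlett_sphericity <- function(data) {
  x <- as.matrix(data)
  n <- nrow(x); p <- ncol(x)
  if (n <= p) abort("Need more observations than variables.")
  R <- cor(x)
  d <- det(R)
  if (!is.finite(d) || d <= .Machine$double.eps) {
    pairs <- which(abs(R) > 1 - 1e-8 & row(R) < col(R), arr.ind = TRUE)
    cols <- unique(c(colnames(R)[pairs[, 1]], colnames(R)[pairs[, 2]]))
    abort(paste0("Correlation matrix is singular (collinear columns: ",
                 paste(cols, collapse = ", "), ")."))
  }
  chisq <- -(n - 1 - (2 * p + 5) / 6) * log(d)
  df <- p * (p - 1) / 2
  tibble(chisq = chisq, df = df,
         p_value = stats::pchisq(chisq, df, lower.tail = FALSE), n = n)
}

# minimum-residual (ULS) extraction: minimize the squared off-diagonal
# residuals of R - Lambda Lambda' over the uniquenesses
minres_extract <- function(R, n_factors) {
  p <- ncol(R)
  loadings_for <- function(psi) {
    R1 <- R
    diag(R1) <- 1 - psi
    e <- eigen(R1, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(n_factors)], 0)
    e$vectors[, seq_len(n_factors), drop = FALSE] %*% diag(sqrt(lam), n_factors)
  }
  objective <- function(psi) {
    L <- loadings_for(psi)
    resid <- R - tcrossprod(L)
    sum(resid[upper.tri(resid)]^2)
  }
  smc <- 1 - 1 / diag(solve(R))
  start <- pmin(pmax(1 - smc, 0.05), 0.95)
  opt <- optim(start, objective, method = "L-BFGS-B",
               lower = 1e-3, upper = 1)
  L <- loadings_for(opt$par)
  rownames(L) <- colnames(R)
  list(loadings = L, uniquenesses = opt$par, objective = opt$value,
       converged = opt$convergence == 0)
}

#' Fit the two-factor autonomic model
#'
#' Extracts factors from the correlation matrix of the autonomic indices
#' by the minimum-residual method, applies a varimax rotation, and
#' labels the factors by their loading pattern: the factor with the
#' larger positive loading mass on RMSSD, SDNN, pNNI-50 and total power
#' is *overall HRV*; the other is *parasympathetic activity* provided it
#' loads positively on RMSSD and normalized HF power and negatively on
#' CSI (otherwise labels are left `NA` with a diagnostic).
#'
#' @param data Numeric data frame of observations x variables (see
#'   [factor_input()]).
#' @param n_factors Number of factors (default 2).
#' @param rotate Apply varimax rotation.
#' @param bartlett_alpha Warn (not abort) when Bartlett's sphericity
#'   p-value is above this gate.
#' @return An object of class `hrv_factors`: rotated loadings,
#'   eigenvalues of the correlation matrix, uniquenesses/communalities,
#'   factor labels, regression scores for the fitting data, and the
#'   Bartlett gate result.
#' @export
fit_hrv_factors <- function(data, n_factors = 2, rotate = TRUE,
                            bartlett_alpha = 0.05) {
  x <- as.matrix(data)
  x <- x[complete.cases(x), , drop = FALSE]
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  const <- apply(x, 2, sd) == 0
  if (any(const)) {
    abort(paste0("Constant columns: ", paste(colnames(x)[const], collapse = ", ")))
  }
  bart <- bartlett_sphericity(x)
  if (bart$p_value > bartlett_alpha) {
    warn(sprintf("Bartlett sphericity p = %.3f: little shared correlation; factors may be meaningless.",
                 bart$p_value))
  }
  R <- cor(x)
  eig <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  fit <- minres_extract(R, n_factors)
  L <- fit$loadings
  rot <- diag(n_factors)
  if (rotate && n_factors > 1) {
    v <- varimax(L, eps = 1e-10)
    L <- L %*% v$rotmat
    rot <- v$rotmat
  }
  # sign convention: each factor points towards positive total loading;
  # the labeling step may re-orient factors (a factor's sign is
  # arbitrary) to match the autonomic sign pattern
  flip <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, flip, `*`)
  colnames(L) <- paste0("F", seq_len(n_factors))

  labels <- label_factors(L)
  L <- sweep(L, 2, labels$orient, `*`)
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  z <- sweep(sweep(x, 2, center), 2, scale_, `/`)
  W <- solve(R, L)           # regression (Thurstone) score weights
  scores <- z %*% W
  colnames(scores) <- colnames(L)

  structure(
    list(loadings = L, rotation = if (rotate) "varimax" else "none",
         extraction = "minres", eigenvalues = eig,
         uniquenesses = setNames(fit$uniquenesses, colnames(R)),
         communalities = setNames(rowSums(L^2), colnames(R)),
         labels = labels$labels, label_diagnostic = labels$diagnostic,
         scores = as_tibble(scores), weights = W,
         center = center, scale = scale_, n_obs = nrow(x),
         objective = fit$objective, converged = fit$converged,
         bartlett = bart),
    class = "hrv_factors"
  )
}

label_factors <- function(L) {
  no_label <- function(diag) {
    list(labels = rep(NA_character_, ncol(L)), orient = rep(1, ncol(L)),
         diagnostic = diag)
  }
  if (ncol(L) != 2 ||
      !all(c("rmssd", "hf_power_norm", "csi") %in% rownames(L))) {
    return(no_label("labeling rule defined for 2 factors over the autonomic index set"))
  }
  overall_vars <- intersect(c("rmssd", "sdnn", "pnni_50", "total_power"),
                            rownames(L))
  # the overall-variability factor carries the larger loading mass on the
  # variability set, oriented positive (factor signs are arbitrary)
  mass <- colSums(L[overall_vars, , drop = FALSE])
  f_over <- which.max(abs(mass))
  f_para <- setdiff(seq_len(2), f_over)
  orient <- rep(1, 2)
  orient[f_over] <- sign(mass[f_over])
  para_ok <- function(v) {
    v["rmssd"] > 0 && v["hf_power_norm"] > 0 && v["csi"] < 0
  }
  if (para_ok(L[, f_para])) {
    orient[f_para] <- 1
  } else if (para_ok(-L[, f_para])) {
    orient[f_para] <- -1
  } else {
    return(no_label(sprintf(
      "second factor sign pattern not met in either orientation (rmssd %.2f, nhf %.2f, csi %.2f)",
      L["rmssd", f_para], L["hf_power_norm", f_para], L["csi", f_para])))
  }
  labels <- character(2)
  labels[f_over] <- "overall_hrv"
  labels[f_para] <- "parasympathetic"
  list(labels = labels, orient = orient, diagnostic = NA_character_)
}

#' Score new observations with a fitted factor model
#'
#' Applies the regression (Thurstone) score weights of a fitted
#' [fit_hrv_factors()] model; observations with any missing variable get
#' `NA` scores.
#'
#' @param model An `hrv_factors` object.
#' @param data Data frame containing the model's variables.
#' @return A tibble of factor scores (named by label when available).
#' @export
score_factors <- function(model, data) {
  stopifnot(inherits(model, "hrv_factors"))
  vars <- rownames(model$loadings)
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0) {
    abort(paste0("`data` lacks variables: ", paste(miss, collapse = ", ")))
  }
  x <- as.matrix(data[, vars])
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, `/`)
  s <- z %*% model$weights
  s[!complete.cases(x), ] <- NA_real_
  colnames(s) <- ifelse(is.na(model$labels), colnames(model$loadings),
                        model$labels)
  as_tibble(s)
}

#' Tucker congruence coefficients between two loading matrices
#'
#' Columns of `b` are matched to columns of `a` greedily by absolute
#' congruence; signs are aligned before reporting.
#'
#' @param a,b Loading matrices with identical row order.
#' @return Named numeric vector, one (signed-aligned) congruence per
#'   factor of `a`.
#' @export
factor_congruence <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  cong <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  k <- ncol(a)
  avail <- seq_len(ncol(b))
  out <- numeric(k)
  for (i in seq_len(k)) {
    cc <- vapply(avail, function(j) cong(a[, i], b[, j]), numeric(1))
    j <- which.max(abs(cc))
    out[i] <- abs(cc[j])
    avail <- avail[-j]
  }
  setNames(out, colnames(a) %||% paste0("F", seq_len(k)))
}

#' Simulate autonomic indices with a two-factor structure
#'
#' Draws observations from the common-factor model `X = F L' + E` with
#' orthogonal standard-normal factors and the loading sign pattern of
#' the autonomic index set (an overall-variability factor and a
#' parasympathetic factor that loads negatively on CSI).
#'
#' @param n Number of observations.
#' @param loadings Optional 7x2 loading matrix (rows in the order of the
#'   autonomic index set).
#' @param seed Integer seed.
#' @return A tibble of the seven indices with attributes `true_loadings`
#'   and `true_scores`.
#' @export
simulate_hrv_factor_data <- function(n, loadings = NULL, seed = 1L) {
  L <- loadings %||% cbind(
    overall_hrv = c(rmssd = 0.75, sdnn = 0.85, pnni_50 = 0.75,
                    total_power = 0.80, hf_power_norm = 0.10,
                    cvi = 0.60, csi = 0.05),
    parasympathetic = c(rmssd = 0.45, sdnn = 0.05, pnni_50 = 0.20,
                        total_power = 0.10, hf_power_norm = 0.80,
                        cvi = 0.45, csi = -0.70)
  )
  psi <- 1 - rowSums(L^2)
  if (any(psi <= 0)) abort("Loadings imply non-positive uniquenesses.")
  set.seed(seed)
  f <- matrix(rnorm(n * ncol(L)), n)
  e <- matrix(rnorm(n * nrow(L)), n) %*% diag(sqrt(psi))
  x <- f %*% t(L) + e
  colnames(x) <- rownames(L)
  out <- as_tibble(x)
  attr(out, "true_loadings") <- L
  attr(out, "true_scores") <- f
  out
}

#' @export
print.hrv_factors <- function(x, ...) {
  cat(sprintf("<hrv_factors: %s + %s, %d obs>\n", x$extraction, x$rotation,
              x$n_obs))
  lab <- ifelse(is.na(x$labels), colnames(x$loadings), x$labels)
  L <- round(x$loadings, 2)
  colnames(L) <- lab
  print(L)
  invisible(x)
}

#' @describeIn fit_hrv_factors Loadings in long (tidy) form.
#' @param x An `hrv_factors` object.
#' @param ... Unused.
#' @export
tidy.hrv_factors <- function(x, ...) {
  L <- x$loadings
  tibble(
    variable = rep(rownames(L), ncol(L)),
    factor = rep(colnames(L), each = nrow(L)),
    label = rep(ifelse(is.na(x$labels), colnames(L), x$labels),
                each = nrow(L)),
    loading = as.vector(L),
    communality = rep(unname(x$communalities), ncol(L))
  )
}

#' @describeIn fit_hrv_factors One-row model summary.
#' @export
glance.hrv_factors <- function(x, ...) {
  tibble(
    n_obs = x$n_obs, n_factors = ncol(x$loadings),
    prop_variance = sum(x$loadings^2) / length(x$communalities),
    bartlett_chisq = x$bartlett$chisq, bartlett_p = x$bartlett$p_value,
    converged = x$converged, labeled = !anyNA(x$labels)
  )
}

#' @describeIn fit_hrv_factors Loading heat map.
#' @param object An `hrv_factors` object.
#' @export
autoplot.hrv_factors <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(.data$label, .data$variable,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$loading))) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading",
                  title = "Rotated factor loadings")
}
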