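# L1-regularized maximum-entropy presence-background model.
# The model is the Gibbs distribution raw(x) = exp(lambda . f(x)) / Z
# over background cells, fitted by maximizing the regularized training
# gain (average presence log-density improvement over the uniform
# background distribution) with coordinate-wise Newton updates and
# soft-thresholding on the L1 penalty.

BETA_DEFAULTS <- c(linear = 0.1, quadratic = 0.1, product = 0.2,
                   hinge = 0.5, categorical = 0.1)

#' Build a hinge / HQP feature specification
#'
#' Each continuous variable is min-max scaled to [0, 1] using the ranges
#' observed in \code{values}; features are the linear term, forward
#' hinges \eqn{\max(0, v - k)/(1 - k)} and reverse hinges
#' \eqn{\max(0, k - v)/k} at \code{n_knots} equally spaced knots strictly
#' inside (0, 1); the HQP class adds per-variable quadratics and all
#' pairwise products. Categorical variables (declared 0/1) enter
#' unscaled with a single linear-class feature.
#'
#' @param values Numeric matrix (rows = locations, cols = variables,
#'   named) used to fix the scaling ranges.
#' @param class_set \code{"H"} (hinge + linear) or \code{"HQP"}.
#' @param n_knots Knots per orientation per variable (default 30).
#' @param categorical Character vector of column names treated as 0/1
#'   categorical layers.
#' @return Object of class \code{chequer_features}: scaling table,
#'   feature table (feature, var, class, knot, orientation).
#' @export
build_features <- function(values, class_set = c("H", "HQP"),
                           n_knots = 30, categorical = character(0)) {
  class_set <- match.arg(class_set)
  values <- as.matrix(values)
  vars <- colnames(values)
  if (is.null(vars)) stop("variable matrix must have column names")
  if (any(!is.finite(values))) stop("non-finite values in variable matrix")
  rng <- apply(values, 2, range)
  zero <- rng[2, ] - rng[1, ] <= 0
  drop_cat <- intersect(vars[zero], categorical)
  if (any(zero & !(vars %in% categorical))) {
    warning("dropping zero-range variable(s): ",
            paste(vars[zero & !(vars %in% categorical)], collapse = ", "))
  }
  keep <- vars[!zero | vars %in% setdiff(categorical, drop_cat)]
  cont <- setdiff(keep, categorical)
  cats <- intersect(keep, categorical)

  knots <- seq_len(n_knots) / (n_knots + 1)
  ft <- list()
  add <- function(var, class, knot = NA_real_, orientation = NA_character_) {
    ft[[length(ft) + 1L]] <<- data.frame(var = var, class = class,
                                         knot = knot,
                                         orientation = orientation,
                                         stringsAsFactors = FALSE)
  }
  for (v in cont) {
    add(v, "linear")
    for (k in knots) {
      add(v, "hinge", k, "forward")
      add(v, "hinge", k, "reverse")
    }
    if (class_set == "HQP") add(v, "quadratic")
  }
  if (class_set == "HQP" && length(cont) > 1) {
    for (a in seq_len(length(cont) - 1)) for (b in (a + 1):length(cont)) {
      ft[[length(ft) + 1L]] <- data.frame(var = cont[a], class = "product",
                                          knot = NA_real_,
                                          orientation = cont[b],
                                          stringsAsFactors = FALSE)
    }
  }
  for (v in cats) add(v, "categorical")
  ft <- do.call(rbind, ft)
  ft$feature <- paste0("f", seq_len(nrow(ft)))
  structure(list(class_set = class_set, n_knots = n_knots,
                 vars = keep, categorical = cats,
                 min = rng[1, keep], max = rng[2, keep], table = ft),
            class = "chequer_features")
}

#' Evaluate a feature specification on raw variable values
#'
#' Values are min-max scaled with the spec's stored ranges (clamped to
#' [0, 1] outside them), so every feature lies in [0, 1].
#'
#' @param spec A \code{chequer_features}.
#' @param values Numeric matrix with at least the spec's variables.
#' @return Numeric feature matrix (rows = locations).
#' @export
feature_matrix <- function(spec, values) {
  values <- as.matrix(values)
  miss <- setdiff(spec$vars, colnames(values))
  if (length(miss)) stop("variables missing from input: ",
                         paste(miss, collapse = ", "))
  sc <- sapply(spec$vars, function(v) {
    if (v %in% spec$categorical) return(values[, v])
    r <- spec$max[v] - spec$min[v]
    pmin(1, pmax(0, (values[, v] - spec$min[v]) / r))
  })
  sc <- matrix(sc, nrow = nrow(values),
               dimnames = list(NULL, spec$vars))
  ft <- spec$table
  out <- matrix(0, nrow(values), nrow(ft),
                dimnames = list(NULL, ft$feature))
  for (j in seq_len(nrow(ft))) {
    v <- sc[, ft$var[j]]
    out[, j] <- switch(ft$class[j],
      linear = v,
      quadratic = v^2,
      categorical = v,
      product = v * sc[, ft$orientation[j]],
      hinge = {
        k <- ft$knot[j]
        if (ft$orientation[j] == "forward") pmax(0, v - k) / (1 - k)
        else pmax(0, k - v) / k
      })
  }
  out
}

# per-feature regularization beta from the class defaults
feature_betas <- function(spec, beta = BETA_DEFAULTS) {
  b <- BETA_DEFAULTS
  b[names(beta)] <- beta
  unname(b[spec$table$class])
}

#' Fit the maximum-entropy model
#'
#' Maximizes \eqn{G(\lambda) = \bar\eta_{pres} - \ln(\overline{e^\eta}_{bg})
#' - \sum_j \beta_j s_j |\lambda_j|} (gain relative to the uniform
#' background distribution; 0 for the null model), where
#' \eqn{\eta = \lambda\cdot f} and \eqn{s_j} is the sample standard
#' deviation of feature j at the presences. Coordinate-wise Newton
#' updates with soft-thresholding; coordinates are cycled in descending
#' order of the initial gradient magnitude. The gain is non-decreasing
#' across updates (asserted).
#'
#' @param fp Feature matrix at presences (m x J, all values in [0, 1]).
#' @param fb Feature matrix at background cells (N x J).
#' @param spec The \code{chequer_features} that produced the matrices.
#' @param beta Named per-class regularization multipliers (defaults:
#'   linear/quadratic 0.1, product 0.2, hinge 0.5, categorical 0.1).
#' @param tol Convergence tolerance on the best single-coordinate gain
#'   improvement (default 1e-6).
#' @param max_iter Maximum full coordinate cycles (default 200).
#' @return Object of class \code{chequer_maxent}: \code{lambda},
#'   \code{spec}, \code{log_zsum}, \code{n_bg}, \code{entropy},
#'   \code{gain}, \code{gain_trace} (per parent variable), \code{eta_bg}.
#' @export
fit_maxent <- function(fp, fb, spec, beta = BETA_DEFAULTS, tol = 1e-6,
                       max_iter = 200) {
  m <- nrow(fp); N <- nrow(fb)
  if (m < 1) stop("need at least one presence")
  if (N < 2) stop("need at least two background cells")
  J <- ncol(fb)
  stopifnot(ncol(fp) == J)
  bmean <- colMeans(fp)
  s <- if (m > 1) apply(fp, 2, stats::sd) else rep(0, J)
  s[!is.finite(s)] <- 0
  # floor the penalty scale at the feature's background range / sqrt(m):
  # a feature constant at the presences is still uncertain (confidence
  # width ~ range/sqrt(m)); without the floor such features carry no
  # penalty and their coefficients diverge
  rng_b <- apply(fb, 2, function(x) diff(range(x)))
  s <- pmax(s, rng_b / sqrt(m))
  bet <- feature_betas(spec, beta) * s

  lambda <- numeric(J)
  eta_b <- numeric(N)
  # order: descending |gradient| at lambda = 0
  ord <- order(-abs(bmean - colMeans(fb)))

  logmeanexp <- function(x) { mx <- max(x); mx + log(mean(exp(x - mx))) }
  gain_fun <- function() {
    sum(lambda * bmean) - logmeanexp(eta_b) - sum(bet * abs(lambda))
  }
  parent <- spec$table$var
  trace <- stats::setNames(numeric(length(spec$vars)), spec$vars)
  gain <- 0
  if (!is.finite(gain_fun())) stop("non-finite gain at initialization")

  for (cycle in seq_len(max_iter)) {
    best_impr <- 0
    for (j in ord) {
      f <- fb[, j]
      w <- exp(eta_b - max(eta_b))
      w <- w / sum(w)
      bj <- bmean[j]
      # Newton solve of h'(delta) = c on the smooth part
      newton <- function(cc) {
        delta <- 0
        for (it in 1:12) {
          u <- w * exp(delta * f - max(delta * f))
          u <- u / sum(u)
          mu <- sum(u * f)
          va <- sum(u * f^2) - mu^2
          if (va < 1e-14) break
          step <- (bj - cc - mu) / va
          step <- max(-10, min(10, step))
          delta <- delta + step
          if (abs(step) < 1e-12) break
        }
        delta
      }
      cand <- c(0, -lambda[j])
      if (bet[j] > 0) {
        dp <- newton(bet[j])
        if (lambda[j] + dp >= 0) cand <- c(cand, dp)
        dn <- newton(-bet[j])
        if (lambda[j] + dn <= 0) cand <- c(cand, dn)
      } else {
        cand <- c(cand, newton(0))
      }
      # exact penalized improvement for each candidate step
      impr <- vapply(cand, function(delta) {
        if (delta == 0) return(0)
        bj * delta - logmeanexp(eta_b + delta * f) + logmeanexp(eta_b) -
          bet[j] * (abs(lambda[j] + delta) - abs(lambda[j]))
      }, numeric(1))
      k <- which.max(impr)
      if (impr[k] > 0) {
        delta <- cand[k]
        lambda[j] <- lambda[j] + delta
        eta_b <- eta_b + delta * f
        trace[parent[j]] <- trace[parent[j]] + impr[k]
        best_impr <- max(best_impr, impr[k])
      }
    }
    new_gain <- gain_fun()
    if (new_gain < gain - 1e-9)
      stop("internal error: gain decreased during coordinate descent")
    gain <- new_gain
    if (best_impr < tol) break
  }

  log_zsum <- {
    mx <- max(eta_b); mx + log(sum(exp(eta_b - mx)))
  }
  raw <- exp(eta_b - log_zsum)
  entropy <- -sum(ifelse(raw > 0, raw * log(raw), 0))
  structure(list(lambda = stats::setNames(lambda, colnames(fb)),
                 spec = spec, log_zsum = log_zsum, n_bg = N,
                 entropy = entropy, gain = gain, gain_trace = trace,
                 eta_bg = eta_b, presence_means = bmean),
            class = "chequer_maxent")
}

#' @export
print.chequer_maxent <- function(x, ...) {
  cat(sprintf("Maxent model: %d features over %s, gain %.4f, entropy %.4f\n",
              length(x$lambda), paste(x$spec$vars, collapse = ", "),
              x$gain, x$entropy))
  invisible(x)
}

# logistic transform of raw scores given the model's entropy:
# L = e^H raw / (1 + e^H raw); the null model maps to 0.5 everywhere.
logistic_from_eta <- function(model, eta) {
  raw <- exp(eta - model$log_zsum)
  q <- exp(model$entropy) * raw
  q / (1 + q)
}

#' Logistic suitability scores at raw variable values
#'
#' @param model A \code{chequer_maxent}.
#' @param values Numeric matrix of raw variable values.
#' @return Numeric vector of logistic outputs in (0, 1).
#' @export
predict_maxent <- function(model, values) {
  fm <- feature_matrix(model$spec, values)
  eta <- as.numeric(fm %*% model$lambda)
  logistic_from_eta(model, eta)
}

#' Logistic suitability raster
#'
#' @param model A \code{chequer_maxent}.
#' @param stack Named list of \code{chequer_raster} layers covering the
#'   model's variables (identical grids).
#' @return A \code{chequer_raster} of logistic values.
#' @export
predict_logistic <- function(model, stack) {
  miss <- setdiff(model$spec$vars, names(stack))
  if (length(miss)) stop("variable(s) missing from stack: ",
                         paste(miss, collapse = ", "))
  sv <- stack_values(stack[model$spec$vars])
  tmpl <- stack[[model$spec$vars[1]]]
  out <- matrix(NA_real_, tmpl$nrows, tmpl$ncols)
  if (nrow(sv$values)) {
    L <- predict_maxent(model, sv$values)
    out[cbind(sv$cells$row, sv$cells$col)] <- L
  }
  raster_grid(out, tmpl$xll, tmpl$yll, tmpl$cellsize, tmpl$nodata)
}
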