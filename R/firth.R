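#' Firth-penalized logistic regression
#'
#' Fits a logistic regression with Jeffreys-prior (Firth) penalization, the
#' standard remedy for the extreme case-control imbalance and complete
#' separation that rare-variant burden tests routinely produce: with a handful
#' of carriers the ordinary maximum-likelihood estimate can be infinite, while
#' the penalized estimate is always finite.
#'
#' The penalized log-likelihood is `l(beta) + 0.5 * log det I(beta)`, with
#' `I` the Fisher information of the full design. The score is solved by
#' Newton-Raphson with per-iteration step capping and step-halving on the
#' penalized likelihood. Setting `fixed` constrains coefficients to zero
#' while keeping the full design's penalty, which is what the penalized
#' likelihood-ratio test of a single coefficient requires (the null is the
#' constrained maximum of the same penalized likelihood, not a refit of the
#' reduced design).
#'
#' Rank deficiency is handled lazily: the fit runs on the full design and
#' only falls back to a QR-based drop of aliased columns (with a warning)
#' when the information matrix fails to factorize.
#'
#' @param x Numeric design matrix including an intercept column.
#' @param y Binary 0/1 response vector.
#' @param start Optional starting coefficient vector (length `ncol(x)`).
#' @param fixed Integer indices of columns whose coefficients are constrained
#'   to zero.
#' @param maxit,tol Iteration cap and convergence tolerance on the free
#'   components of the penalized score.
#'
#' @return A list with `coefficients`, `vcov` (inverse penalized information),
#'   `loglik_penalized`, `iter`, `converged`, and `rank_dropped` (names of any
#'   aliased columns removed, with a warning).
#' @keywords internal
firth_logistic <- function(x, y, start = NULL, fixed = integer(0),
                           maxit = 50L, tol = 1e-6) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort("response must be binary 0/1")

  tryCatch(
    firth_core(x, y, start, fixed, maxit, tol, dropped = character()),
    ppvscreen_singular = function(cnd) {
      qx <- qr(x)
      if (qx$rank == ncol(x)) {
        # numerically awkward but full rank: retry with a tiny ridge
        return(firth_core(x, y, start, fixed, maxit, tol,
                          dropped = character(), ridge = 1e-8))
      }
      keep <- sort(qx$pivot[seq_len(qx$rank)])
      dropped <- colnames(x)[-keep]
      warn(paste("dropping collinear column(s):",
                 paste(dropped, collapse = ", ")))
      fixed2 <- match(intersect(colnames(x)[fixed], colnames(x)[keep]),
                      colnames(x)[keep])
      firth_core(x[, keep, drop = FALSE], y, start[keep],
                 fixed2[!is.na(fixed2)], maxit, tol, dropped = dropped)
    })
}

firth_core <- function(x, y, start, fixed, maxit, tol, dropped, ridge = 0) {
  n <- nrow(x)
  p <- ncol(x)
  free <- setdiff(seq_len(p), fixed)

  beta <- if (!is.null(start)) as.numeric(start) else {
    b0 <- numeric(p)
    pbar <- min(max(mean(y), 1 / (n + 2)), 1 - 1 / (n + 2))
    ic <- which(apply(x, 2, function(col) all(col == 1)))[1]
    if (!is.na(ic)) b0[ic] <- log(pbar / (1 - pbar))
    b0
  }
  beta[fixed] <- 0

  state <- function(beta) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    info <- crossprod(x, x * w)
    if (ridge > 0) info <- info + diag(ridge, p)
    ch <- tryCatch(chol(info), error = function(e) {
      abort("singular information matrix", class = "ppvscreen_singular")
    })
    d <- diag(ch)
    if (ridge == 0 && (any(!is.finite(d)) || min(d) < 1e-7 * max(d))) {
      # chol can "succeed" on an aliased design through rounding alone
      abort("singular information matrix", class = "ppvscreen_singular")
    }
    # log(1 + e^eta) = max(eta, 0) + log1p(e^{-|eta|}), overflow-safe
    ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))) +
      sum(log(diag(ch)))
    list(mu = mu, w = w, ch = ch, ll = ll)
  }

  maxstep <- 5   # per-iteration cap on the coefficient move, prevents
                 # overshooting onto the flat penalized plateau at separation
  st <- state(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    inv <- chol2inv(st$ch)
    h <- rowSums((x %*% inv) * x) * st$w
    score <- drop(crossprod(x, y - st$mu + h * (0.5 - st$mu)))[free]
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    info_free <- crossprod(st$ch[, free, drop = FALSE])
    delta <- numeric(p)
    delta[free] <- solve(info_free, score)
    big <- max(abs(delta))
    if (big > maxstep) delta <- delta * (maxstep / big)
    step <- 1
    improved <- FALSE
    while (step >= 1e-4) {
      cand <- beta + step * delta
      st_new <- state(cand)
      if (is.finite(st_new$ll) && st_new$ll > st$ll + 1e-12) {
        improved <- TRUE; break
      }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }  # no ascent direction left
    gain <- st_new$ll - st$ll
    beta <- cand
    st <- st_new
    # Newton is locally quadratic: a sub-1e-9 gain means the next step would
    # change the penalized likelihood (and any LRT built on it) negligibly
    if (gain < 1e-9 || max(abs(step * delta)) < 1e-10) {
      converged <- TRUE; break
    }
  }

  names(beta) <- colnames(x)
  vcov <- chol2inv(st$ch)
  dimnames(vcov) <- list(colnames(x), colnames(x))
  list(coefficients = beta, vcov = vcov, loglik_penalized = st$ll,
       iter = iter, converged = converged, rank_dropped = dropped)
}
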