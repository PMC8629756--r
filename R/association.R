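#' Assemble the association covariate set
#'
#' Builds the standard covariate matrix: age, sex, age*sex, age^2 and
#' sex*age^2, with derived terms always recomputed from age and sex. Age is
#' internally standardized, which leaves the burden term's estimate and test
#' untouched (the span of the age polynomial and its sex interactions is
#' invariant to affine rescaling) while keeping the information matrix well
#' conditioned.
#'
#' @param samples Manifest tibble with `sample_id`, `age` (years) and `sex`
#'   (`"F"`/`"M"` or 0/1, 1 = female).
#' @param extra Optional numeric matrix or tibble of additional covariates
#'   (e.g. ancestry components, pipeline version indicator), one row per
#'   sample in manifest order.
#' @param include_sex Drop the sex terms (for sex-restricted phenotypes)
#'   when `FALSE`.
#' @return Numeric matrix, one row per sample, no missing values.
#' @export
build_covariates <- function(samples, extra = NULL, include_sex = TRUE) {
  age <- as.numeric(samples$age)
  sex <- samples$sex
  if (is.character(sex) || is.factor(sex)) sex <- as.numeric(sex == "F")
  sex <- as.numeric(sex)
  if (any(is.na(age)) || any(is.na(sex))) {
    abort("covariates must have no missing values after assembly")
  }
  a <- (age - mean(age)) / max(stats::sd(age), 1e-8)
  m <- if (include_sex) {
    cbind(age = a, sex = sex, age_sex = a * sex, age2 = a^2, sex_age2 = sex * a^2)
  } else {
    cbind(age = a, age2 = a^2)
  }
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    if (nrow(extra) != nrow(m)) abort("`extra` covariates must match manifest rows")
    if (any(is.na(extra))) abort("covariates must have no missing values after assembly")
    m <- cbind(m, extra)
  }
  m
}

#' Firth-penalized burden association test
#'
#' Tests one gene's 0/1 burden indicator against one 0/1 phenotype with
#' covariate adjustment, using Firth-penalized logistic regression so that
#' estimates stay finite under the complete separation and extreme
#' case-control imbalance typical of rare-variant carriers. The default
#' p-value is a penalized likelihood-ratio test; a Wald test is available.
#'
#' @param burden Integer/numeric 0/1 carrier indicator.
#' @param pheno Integer/numeric 0/1 case indicator.
#' @param covariates Optional numeric covariate matrix (see
#'   [build_covariates()]); `NULL` fits an intercept-only adjustment.
#' @param method `"LRT"` (default) or `"Wald"`.
#' @param null_fit Optional precomputed Firth fit of the covariate-only model,
#'   reused across genes sharing a phenotype.
#' @return An object of class `burden_fit`: list with `beta`, `se`, `z`
#'   (signed, `sign(z) == sign(beta)`), `p` (two-sided), `n`, `method`,
#'   `converged`. [tidy()] returns a one-row tibble.
#' @examples
#' set.seed(1)
#' b <- rbinom(500, 1, 0.02); y <- rbinom(500, 1, 0.1 + 0.5 * b)
#' tidy(fit_burden_test(b, y))
#' @export
fit_burden_test <- function(burden, pheno, covariates = NULL,
                            method = c("LRT", "Wald"), null_fit = NULL) {
  method <- match.arg(method)
  burden <- as.numeric(burden)
  pheno <- as.numeric(pheno)
  if (length(burden) != length(pheno)) abort("burden and phenotype lengths differ")
  if (sum(burden) < 1) abort("no carriers: burden test requires >= 1 carrier")
  if (length(unique(pheno)) < 2L) {
    abort("constant phenotype: association skipped",
          class = "ppvscreen_constant_phenotype")
  }
  x0 <- cbind(`(Intercept)` = rep(1, length(pheno)), covariates)
  x1 <- cbind(x0, burden = burden)
  if (is.null(null_fit)) null_fit <- firth_logistic(x0, pheno)
  start <- c(null_fit$coefficients, 0)[colnames(x1)]
  start[is.na(start)] <- 0
  names(start) <- colnames(x1)
  fit <- firth_logistic(x1, pheno, start = start)
  if ("burden" %in% fit$rank_dropped) {
    abort("burden indicator is collinear with the covariates; test undefined")
  }
  beta <- unname(fit$coefficients["burden"])
  se <- sqrt(fit$vcov["burden", "burden"])
  ok <- fit$converged
  if (method == "LRT") {
    # constrained maximum of the SAME penalized likelihood (burden fixed at 0);
    # refitting the reduced design with its own penalty miscalibrates the test
    constrained <- suppressWarnings(  # any rank drop was already reported
      firth_logistic(x1, pheno, start = start,
                     fixed = which(colnames(x1) == "burden")))
    stat <- max(0, 2 * (fit$loglik_penalized - constrained$loglik_penalized))
    z <- sign(beta) * sqrt(stat)
    p <- pchisq(stat, df = 1L, lower.tail = FALSE)
    ok <- ok && constrained$converged
  } else {
    z <- beta / se
    p <- 2 * pnorm(-abs(z))
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(beta = beta, se = se, z = z, p = p, n = length(pheno),
                 method = method, converged = ok),
            class = "burden_fit")
}

#' @export
print.burden_fit <- function(x, ...) {
  cat(sprintf("<burden_fit> beta=%.4g se=%.4g z=%.3f p=%.3g (%s, n=%d)\n",
              x$beta, x$se, x$z, x$p, x$method, x$n))
  invisible(x)
}

#' @rdname fit_burden_test
#' @param x A `burden_fit`.
#' @param ... Unused.
#' @export
tidy.burden_fit <- function(x, ...) {
  tibble::tibble(term = "burden", estimate = x$beta, std.error = x$se,
                 statistic = x$z, p.value = x$p)
}

#' @rdname fit_burden_test
#' @export
glance.burden_fit <- function(x, ...) {
  tibble::tibble(nobs = x$n, method = x$method, converged = x$converged)
}

#' Carrier-by-case contingency table and odds ratio
#'
#' Cross-tabulates the burden indicator against the case indicator and
#' computes the odds ratio `(a*d)/(b*c)` (a = carrier cases, b = carrier
#' controls, c = non-carrier cases, d = non-carrier controls). When any cell
#' is zero the Haldane-Anscombe correction adds 0.5 to every cell, keeping
#' the odds ratio finite.
#'
#' @inheritParams fit_burden_test
#' @return One-row tibble with `a`, `b`, `c`, `d`, `odds_ratio`.
#' @examples
#' contingency_stats(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
contingency_stats <- function(burden, pheno) {
  burden <- as.numeric(burden); pheno <- as.numeric(pheno)
  a <- sum(burden == 1 & pheno == 1)
  b <- sum(burden == 1 & pheno == 0)
  cc <- sum(burden == 0 & pheno == 1)
  d <- sum(burden == 0 & pheno == 0)
  if (a + b + cc + d == 0) abort("empty table")
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  tibble::tibble(a = a, b = b, c = cc, d = d,
                 odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]))
}

#' Positive predictive value of carrier status for a phenotype
#'
#' The PPV — the fraction of carriers who are cases — is the empirical
#' penetrance of qualifying variants in the gene. It can be computed over all
#' ages or restricted to samples aged 60+ (a lifetime-risk approximation).
#' A stratum with zero carriers yields an undefined PPV, reported as `NA`
#' (distinct from 0).
#'
#' @inheritParams fit_burden_test
#' @param ages Numeric current ages, parallel to `burden`.
#' @param stratum `"all"` or `"sixty_plus"`.
#' @param age_cut Lower bound of the lifetime-risk stratum (default 60).
#' @return One-row tibble with `ppv`, `carriers`, `carrier_cases`.
#' @examples
#' compute_ppv(c(1, 1, 1, 1, 0), c(1, 1, 1, 0, 1), ages = rep(70, 5))
#' @export
compute_ppv <- function(burden, pheno, ages, stratum = c("all", "sixty_plus"),
                        age_cut = 60) {
  stratum <- match.arg(stratum)
  keep <- if (stratum == "sixty_plus") ages >= age_cut else rep(TRUE, length(burden))
  b <- as.numeric(burden)[keep]; y <- as.numeric(pheno)[keep]
  carriers <- sum(b == 1)
  cc <- sum(b == 1 & y == 1)
  tibble::tibble(ppv = if (carriers == 0) NA_real_ else cc / carriers,
                 carriers = carriers, carrier_cases = cc)
}

#' Per-cohort gene-by-phenotype association scan
#'
#' Runs the Firth burden test for every gene with at least one carrier
#' against every analysis phenotype, and attaches the 2x2 counts, odds ratio
#' and stratified PPVs needed downstream by the meta-analysis and the PPV
#' screen. Phenotypes that are constant in the cohort are skipped.
#'
#' @param burden A `burden_matrix` (see [collapse_burden()]).
#' @param phenotypes A `phenotype_matrix` (see [map_diagnoses()]).
#' @param samples Manifest with `sample_id`, `age`, `sex` (rows must match
#'   the burden matrix).
#' @param phecodes Phenotypes to test (default: all columns).
#' @param genes Genes to test (default: all columns).
#' @inheritParams fit_burden_test
#' @inheritParams qualify_variants
#' @param extra_covariates Optional extra covariate matrix.
#' @param sex_specific Optional named character vector mapping a phecode to
#'   `"F"` or `"M"`; the cohort is restricted to that sex for the phenotype
#'   and the sex covariate terms are dropped.
#' @return Tibble with one row per tested (gene, phecode): `gene_id`,
#'   `phecode`, `model`, `n`, `n_cases`, `carriers`, `a`, `b`, `c`, `d`,
#'   `beta`, `se`, `z`, `p`, `odds_ratio`, `ppv_all_ages`, `ppv_60plus`,
#'   `carrier_cases_60plus`, `converged`.
#' @export
associate_cohort <- function(burden, phenotypes, samples, phecodes = NULL,
                             genes = NULL, thresholds = NULL,
                             method = c("LRT", "Wald"),
                             extra_covariates = NULL, sex_specific = NULL) {
  t <- as_thresholds(thresholds)
  method <- match.arg(method)
  stopifnot(inherits(burden, "burden_matrix"),
            inherits(phenotypes, "phenotype_matrix"))
  if (!identical(rownames(burden), samples$sample_id) ||
      !identical(rownames(phenotypes), samples$sample_id)) {
    abort("burden, phenotype and manifest sample orders must agree")
  }
  if (is.null(phecodes)) phecodes <- colnames(phenotypes)
  if (is.null(genes)) genes <- colnames(burden)
  bm <- unclass(burden); pm <- unclass(phenotypes)
  counts <- colSums(bm[, genes, drop = FALSE])
  genes <- genes[counts >= 1L]
  ages <- as.numeric(samples$age)
  sexf <- if (is.character(samples$sex)) samples$sex == "F" else samples$sex == 1

  out <- vector("list", 0L)
  for (ph in phecodes) {
    restrict <- sex_specific[[ph]] %||% NA_character_
    if (!is.na(restrict)) {
      keep <- if (restrict == "F") sexf else !sexf
      extra_k <- if (is.null(extra_covariates)) NULL else
        extra_covariates[keep, , drop = FALSE]
      covs <- build_covariates(samples[keep, ], extra_k, include_sex = FALSE)
    } else {
      keep <- rep(TRUE, nrow(samples))
      covs <- build_covariates(samples, extra_covariates)
    }
    y <- pm[keep, ph]
    if (length(unique(y)) < 2L) {
      inform(sprintf("phecode %s is constant in this cohort; skipped", ph))
      next
    }
    x0 <- cbind(`(Intercept)` = 1, covs)
    null_fit <- firth_logistic(x0, y)
    for (g in genes) {
      b <- bm[keep, g]
      if (sum(b) < 1L) next
      fit <- fit_burden_test(b, y, covs, method = method, null_fit = null_fit)
      ct <- contingency_stats(b, y)
      p_all <- compute_ppv(b, y, ages[keep], "all", t$age_stratum_cut)
      p_60 <- compute_ppv(b, y, ages[keep], "sixty_plus", t$age_stratum_cut)
      out[[length(out) + 1L]] <- tibble::tibble(
        gene_id = g, phecode = ph, model = attr(burden, "model"),
        n = fit$n, n_cases = sum(y), carriers = sum(b),
        a = ct$a, b = ct$b, c = ct$c, d = ct$d,
        beta = fit$beta, se = fit$se, z = fit$z, p = fit$p,
        odds_ratio = ct$odds_ratio,
        ppv_all_ages = p_all$ppv, ppv_60plus = p_60$ppv,
        carrier_cases_60plus = p_60$carrier_cases,
        converged = fit$converged)
    }
  }
  if (length(out) == 0L) return(empty_assoc_table())
  dplyr::bind_rows(out)
}

empty_assoc_table <- function() {
  tibble::tibble(gene_id = character(), phecode = character(),
                 model = character(), n = integer(), n_cases = integer(),
                 carriers = integer(), a = integer(), b = integer(),
                 c = integer(), d = integer(), beta = numeric(),
                 se = numeric(), z = numeric(), p = numeric(),
                 odds_ratio = numeric(), ppv_all_ages = numeric(),
                 ppv_60plus = numeric(), carrier_cases_60plus = integer(),
                 converged = logical())
}
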