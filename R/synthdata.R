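#' Declare a marginal distribution for cohort simulation
#'
#' A marginal spec parameterises one simulated variable: a binary class
#' with a prevalence, or a continuous assay value with a target mean and
#' standard deviation inside a valid range. Continuous marginals are drawn
#' from a range-truncated normal whose underlying parameters are
#' moment-matched so that the TRUNCATED distribution attains the specified
#' mean and sd (see [simulate_cohort()] for the fallback families used when
#' no truncated normal can).
#'
#' @param name Variable name.
#' @param kind `"binary"` or `"continuous"`.
#' @param prevalence For binary: probability of the first level, in
#'   `[0, 1]`.
#' @param levels For binary: the two class labels (first = the class whose
#'   prevalence is given).
#' @param mean,sd For continuous: target moments of the generated values
#'   (`sd = 0` yields the constant `mean`).
#' @param valid_range For continuous: interval the values must respect,
#'   e.g. `c(0, 100)` for a methylation percentage, `c(0, Inf)` for a
#'   concentration.
#' @param tissue,units Metadata forwarded to the cohort schema.
#' @return An object of class `"marginal_spec"`.
#' @export
marginal_spec <- function(name, kind = c("continuous", "binary"),
                          prevalence = NULL, levels = NULL,
                          mean = NULL, sd = NULL, valid_range = c(0, 100),
                          tissue = "none", units = "") {
  kind <- match.arg(kind)
  if (kind == "binary") {
    stopifnot(length(prevalence) == 1L, prevalence >= 0, prevalence <= 1,
              length(levels) == 2L)
    mean <- sd <- valid_range <- NULL
  } else {
    stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0,
              length(valid_range) == 2L,
              mean >= valid_range[1], mean <= valid_range[2])
    prevalence <- levels <- NULL
  }
  structure(list(name = name, kind = kind, prevalence = prevalence,
                 levels = levels, mean = mean, sd = sd,
                 valid_range = valid_range, tissue = tissue, units = units),
            class = "marginal_spec")
}

#' Packaged default marginals of the mother-placenta-neonate cohort
#'
#' The default parameter set of the simulator: 8 binary questionnaire
#' parameters (prevalences of suboptimal birth weight, stressful events,
#' maternal age, environmental exposure, fever/flu, living context, smoking
#' and passive smoking), 15 gene-specific methylation percentages in each
#' of placenta, maternal and neonatal buccal cells plus global 5-mC and
#' 5-hmC content per tissue (51 continuous marginals on `[0, 100]`%), and 8
#' placental metal concentrations plus a dioxin/dioxin-like-PCB
#' toxic-equivalency concentration (9 nonnegative marginals). Vanadium is
#' degenerate (0 +/- 0) and generates a constant column, exercising the
#' constant-node policy of [encode_cohort()].
#'
#' @return List of 68 [marginal_spec()] objects.
#' @examples
#' margins <- default_margins()
#' margins[["H19_placenta"]]
#' @export
default_margins <- function() {
  bin <- list(
    list("birth_weight", 0.214, c("suboptimal", "adequate")),
    list("stressful_events", 0.322, c("yes", "no")),
    list("maternal_age", 0.893, c("under40", "40plus")),
    list("environmental_exposure", 0.107, c("yes", "no")),
    list("fever_flu", 0.286, c("yes", "no")),
    list("living_context", 0.322, c("rural", "urban")),
    list("smoking_before_conception", 0.250, c("yes", "no")),
    list("passive_smoking", 0.214, c("yes", "no")))

  # gene: placenta, maternal buccal, neonatal buccal (mean, sd) in % on [0,100]
  meth <- list(
    BDNF = c(6.92, 7.94, 10.47, 10.13, 7.71, 8.22),
    CYP1A1 = c(19.65, 9.90, 26.71, 6.92, 15.23, 7.31),
    DNMT3B = c(5.02, 5.58, 7.36, 11.00, 7.41, 7.76),
    ERa = c(0.55, 1.11, 5.97, 6.95, 8.48, 11.34),
    H19 = c(58.32, 10.57, 73.60, 11.80, 66.56, 16.52),
    HSD11B2 = c(5.16, 4.22, 0.99, 2.62, 1.96, 3.60),
    IGF2 = c(50.35, 8.00, 39.64, 11.38, 33.88, 11.03),
    LEP = c(65.62, 17.96, 11.48, 6.06, 4.93, 4.62),
    MECP2 = c(7.04, 5.86, 34.22, 13.88, 11.44, 9.65),
    MGMT = c(0.47, 0.56, 0.16, 0.30, 0.33, 0.59),
    MTHFR = c(10.47, 3.73, 17.76, 7.91, 9.41, 6.88),
    OXTR = c(1.23, 1.72, 1.85, 3.17, 1.20, 1.28),
    RELN = c(2.42, 3.10, 3.45, 4.14, 4.02, 3.71),
    NR3C1 = c(23.81, 18.57, 5.95, 4.35, 6.75, 4.74),
    COMT = c(30.56, 9.77, 49.43, 23.67, 8.32, 8.60),
    global_5mC = c(4.90, 2.74, 3.53, 2.69, 3.55, 2.57),
    global_5hmC = c(0.38, 0.49, 0.18, 0.24, 0.24, 0.31))

  # placental concentrations, nonnegative (mean, sd)
  conc <- list(
    silver = c(0.004, 0.007, "mg/kg"),
    nickel = c(0.03, 0.02, "mg/kg"),
    vanadium = c(0, 0, "mg/kg"),
    mercury = c(0.029, 0.02, "mg/kg"),
    arsenic = c(0.001, 0.003, "mg/kg"),
    chromium = c(0.09, 0.07, "mg/kg"),
    cadmium = c(0.033, 0.017, "mg/kg"),
    lead = c(0.052, 0.058, "mg/kg"),
    dioxins_pcbdl = c(0.07, 0.11, "pg TEQ/g"))

  out <- list()
  for (b in bin) {
    out[[b[[1]]]] <- marginal_spec(b[[1]], "binary", prevalence = b[[2]],
                                   levels = b[[3]])
  }
  tissues <- c("placenta", "maternal_buccal", "neonatal_buccal")
  for (g in names(meth)) {
    p <- meth[[g]]
    for (k in 1:3) {
      nm <- paste0(g, "_", tissues[k])
      out[[nm]] <- marginal_spec(nm, "continuous",
                                 mean = p[2 * k - 1], sd = p[2 * k],
                                 valid_range = c(0, 100),
                                 tissue = tissues[k], units = "%")
    }
  }
  for (m in names(conc)) {
    p <- conc[[m]]
    out[[m]] <- marginal_spec(m, "continuous",
                              mean = as.numeric(p[1]), sd = as.numeric(p[2]),
                              valid_range = c(0, Inf),
                              tissue = "placenta", units = p[3])
  }
  out
}

#' Declare a planted dependence structure
#'
#' Dependence is induced through a Gaussian copula: a latent multivariate
#' standard normal with a block correlation structure, transformed
#' coordinate-wise to the declared marginals. Blocks are sets of variable
#' names sharing a within-block latent correlation; everything else gets
#' the background correlation (default 0).
#'
#' @param blocks List of blocks, each a list with `members` (character
#'   vector of marginal names) and `correlation` (within-block latent
#'   correlation in `[-1, 1]`).
#' @param background Latent correlation between all non-co-blocked pairs.
#' @return An object of class `"dependence_spec"`.
#' @export
dependence_spec <- function(blocks = list(), background = 0) {
  stopifnot(background >= -1, background <= 1)
  for (b in blocks) {
    stopifnot(is.character(b$members), length(b$members) >= 2,
              b$correlation >= -1, b$correlation <= 1)
  }
  structure(list(blocks = blocks, background = background),
            class = "dependence_spec")
}

#' Simulation configuration for a synthetic cohort
#'
#' @param n_subjects Number of subject records (default 28, the enrolled
#'   study size the generator mirrors).
#' @param seed Integer seed; the same configuration always yields the
#'   identical cohort.
#' @param marginals List of [marginal_spec()]; defaults to the packaged
#'   questionnaire/methylation/exposure set ([default_margins()]).
#' @param dependence A [dependence_spec()]; default independent margins.
#' @return An object of class `"cohort_sim_config"`.
#' @export
cohort_sim_config <- function(n_subjects = 28, seed = 1,
                              marginals = default_margins(),
                              dependence = dependence_spec()) {
  stopifnot(n_subjects >= 1, length(marginals) >= 1,
            inherits(dependence, "dependence_spec"))
  names(marginals) <- vapply(marginals, function(m) m$name, character(1))
  structure(list(n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed),
                 marginals = marginals, dependence = dependence),
            class = "cohort_sim_config")
}

#' Echo the generative block structure of a configuration
#'
#' Returns the planted dependence structure, for scoring how well a
#' downstream map recovered it.
#'
#' @param config A [cohort_sim_config()].
#' @return The config's [dependence_spec()].
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  config$dependence
}

# ---- truncated-normal moment matching --------------------------------------

# Mean and sd of N(mu, sigma^2) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  if (!is.finite(Z) || Z < 1e-12) return(c(NA_real_, NA_real_))
  da <- stats::dnorm(al); db <- stats::dnorm(be)
  aa <- if (is.finite(al)) al * da else 0
  bb <- if (is.finite(be)) be * db else 0
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (aa - bb) / Z - ((da - db) / Z)^2)
  if (!is.finite(v) || v <= 0) return(c(m, NA_real_))
  c(m, sqrt(v))
}

# Solve for (mu, sigma) so the [a,b]-truncated normal has the target
# mean/sd. Returns NULL when the family cannot attain them (e.g. a
# coefficient of variation above the exponential limit of a hard-truncated
# tail).
match_truncnorm <- function(mean, sd, a, b, rel_tol = 1e-6) {
  scale <- max(sd, 1e-6)
  obj <- function(par) {
    ms <- truncnorm_moments(par[1], exp(par[2]), a, b)
    if (anyNA(ms)) return(1e6)
    ((ms[1] - mean) / scale)^2 + ((ms[2] - sd) / scale)^2
  }
  starts <- list(c(mean, log(sd)),
                 c(mean - sd, log(sd)),
                 c(mean + sd, log(sd)),
                 c(mean - 2 * sd, log(2 * sd)),
                 c(mean, log(sd / 2)))
  best <- NULL
  for (s0 in starts) {
    fit <- stats::optim(s0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
    if (best$value < (rel_tol / 10)^2) break
  }
  if (sqrt(best$value) > rel_tol) return(NULL)
  list(mu = best$par[1], sigma = exp(best$par[2]))
}

# Resolve a continuous marginal to a quantile function u in (0,1) -> value.
# Truncated normal where moment-matching is feasible; otherwise a
# moment-matched gamma (half-open range) or scaled beta (bounded range).
marginal_quantile <- function(spec) {
  a <- spec$valid_range[1]; b <- spec$valid_range[2]
  m <- spec$mean; s <- spec$sd
  if (s == 0) {
    return(list(family = "constant", q = function(u) rep(m, length(u))))
  }
  tn <- match_truncnorm(m, s, a, b)
  if (!is.null(tn)) {
    pa <- stats::pnorm(a, tn$mu, tn$sigma)
    pb <- stats::pnorm(b, tn$mu, tn$sigma)
    return(list(family = "truncnorm", mu = tn$mu, sigma = tn$sigma,
                q = function(u) {
                  x <- stats::qnorm(pa + u * (pb - pa), tn$mu, tn$sigma)
                  pmin(pmax(x, a), b)
                }))
  }
  if (!is.finite(b)) {
    shape <- ((m - a) / s)^2
    rate <- (m - a) / s^2
    return(list(family = "gamma", shape = shape, rate = rate,
                q = function(u) a + stats::qgamma(u, shape, rate)))
  }
  m1 <- (m - a) / (b - a); s1 <- s / (b - a)
  if (s1^2 >= m1 * (1 - m1)) {
    stop("marginal '", spec$name, "': sd ", s,
         " is not attainable inside [", a, ", ", b, "]", call. = FALSE)
  }
  k <- m1 * (1 - m1) / s1^2 - 1
  sh1 <- m1 * k; sh2 <- (1 - m1) * k
  list(family = "beta", shape1 = sh1, shape2 = sh2,
       q = function(u) a + (b - a) * stats::qbeta(u, sh1, sh2))
}

# Latent correlation matrix implied by a dependence spec.
latent_correlation <- function(dependence, names) {
  K <- length(names)
  R <- matrix(dependence$background, K, K, dimnames = list(names, names))
  diag(R) <- 1
  for (blk in dependence$blocks) {
    miss <- setdiff(blk$members, names)
    if (length(miss)) {
      stop("dependence block names unknown marginals: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    idx <- match(blk$members, names)
    R[idx, idx][upper.tri(R[idx, idx])] <- blk$correlation
    R[idx, idx][lower.tri(R[idx, idx])] <- blk$correlation
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("dependence structure implies a non-positive-semi-definite ",
         "latent correlation matrix", call. = FALSE)
  }
  R
}

#' Simulate a synthetic mother-placenta-neonate cohort
#'
#' Draws a latent multivariate standard normal with the configured block
#' correlation structure and maps each coordinate through its marginal:
#' binary variables by thresholding at the prevalence quantile, continuous
#' variables through a range-respecting quantile transform whose underlying
#' parameters are moment-matched so the generated distribution has the
#' specified mean and sd. The truncated normal is used wherever its two
#' moments can be matched inside the valid range; marginals whose
#' coefficient of variation exceeds what any truncated normal can attain
#' (several near-zero methylation and trace-metal marginals) fall back to a
#' moment-matched gamma (half-open range) or scaled beta (bounded range).
#' Degenerate `sd = 0` marginals generate the constant value. Deterministic
#' given the seed.
#'
#' @param config A [cohort_sim_config()].
#' @return A validated [cohort_table()] with one column per marginal.
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(n_subjects = 28, seed = 7))
#' dim(cohort)
#' mean(cohort$data$H19_placenta)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  marginals <- config$marginals
  K <- length(marginals)
  n <- config$n_subjects
  nm <- names(marginals)

  independent <- length(config$dependence$blocks) == 0 &&
    config$dependence$background == 0

  z <- with_local_seed(config$seed, {
    zz <- matrix(stats::rnorm(n * K), n, K)
    if (!independent) {
      R <- latent_correlation(config$dependence, nm)
      U <- chol(R + diag(1e-10, K))
      zz <- zz %*% U
      # restore unit latent variances perturbed by the ridge
      zz <- sweep(zz, 2, sqrt(diag(crossprod(U))), "/")
    }
    zz
  })
  u <- stats::pnorm(z)

  cols <- vector("list", K)
  for (k in seq_len(K)) {
    sp <- marginals[[k]]
    if (sp$kind == "binary") {
      cols[[k]] <- ifelse(u[, k] < sp$prevalence, sp$levels[1], sp$levels[2])
    } else {
      cols[[k]] <- marginal_quantile(sp)$q(u[, k])
    }
  }
  names(cols) <- nm
  data <- as.data.frame(cols, check.names = FALSE, optional = TRUE,
                        stringsAsFactors = FALSE)
  if (n == 0) data <- data[0, , drop = FALSE]

  specs <- lapply(marginals, function(sp) {
    if (sp$kind == "binary") {
      variable_spec(sp$name, "binary", tissue = sp$tissue, units = sp$units,
                    levels = sp$levels)
    } else {
      variable_spec(sp$name, "continuous", tissue = sp$tissue,
                    units = sp$units, valid_range = sp$valid_range)
    }
  })
  cohort_table(data, unname(specs))
}
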