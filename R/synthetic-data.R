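#' Design for a synthetic coexpression data set
#'
#' Describes a planted-structure expression experiment: groups of genes share a
#' latent factor (one per module) so that the expected pairwise within-module
#' Pearson correlation equals `within_module_cor`; a designated fraction of
#' each module's genes are "hubs" with elevated factor loading; background
#' genes are independent noise; an optional quantitative trait is driven by the
#' latent factor of the module containing `trait_genes`.
#'
#' Under the factor model \eqn{x = \lambda f + \epsilon} with
#' \eqn{\epsilon \sim N(0, \sigma^2)}, the population correlation between two
#' module members is \eqn{\lambda^2 / (\lambda^2 + \sigma^2)}, so the loading
#' is set to \eqn{\lambda = \sigma \sqrt{\rho / (1 - \rho)}} to hit the target
#' \eqn{\rho}. Hub genes use loading `hub_loading * lambda`.
#'
#' @param n_genes total number of genes.
#' @param n_samples number of samples (columns).
#' @param module_sizes integer vector of planted module sizes; must sum to at
#'   most `n_genes`. Remaining genes are uncorrelated background.
#' @param within_module_cor target within-module Pearson correlation, in
#'   (0, 1); scalar or one value per module.
#' @param hub_fraction fraction of each module's genes given elevated loading.
#' @param hub_loading loading multiplier for hub genes (> 1 strengthens hubs).
#' @param trait_genes indices of genes whose module factor drives the trait;
#'   must all belong to one planted module. Empty means the trait is pure
#'   noise.
#' @param trait_effect slope of the trait on the latent factor.
#' @param trait_noise_sd residual standard deviation of the trait.
#' @param noise_sd residual standard deviation of expression (log2 units).
#' @param baseline_mean baseline log2 expression level added to every gene.
#' @param seed integer RNG seed; generation is reproducible given the seed.
#' @return An object of class `synthetic_design`.
#' @seealso [generate_expression()]
#' @export
synthetic_design <- function(n_genes,
                             n_samples,
                             module_sizes = integer(0),
                             within_module_cor = 0.8,
                             hub_fraction = 0.1,
                             hub_loading = 1.5,
                             trait_genes = integer(0),
                             trait_effect = 0,
                             trait_noise_sd = 1,
                             noise_sd = 1,
                             baseline_mean = 8,
                             seed = 1L) {
  fail <- function(field, msg)
    stop("invalid design: field '", field, "' ", msg, call. = FALSE)
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1 ||
      n_genes != round(n_genes))
    fail("n_genes", "must be a positive integer")
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1 ||
      n_samples != round(n_samples))
    fail("n_samples", "must be a positive integer")
  module_sizes <- as.integer(module_sizes)
  if (any(module_sizes < 0)) fail("module_sizes", "must be non-negative")
  module_sizes <- module_sizes[module_sizes > 0]
  if (sum(module_sizes) > n_genes)
    fail("module_sizes", "must sum to at most n_genes")
  k <- length(module_sizes)
  if (!is.numeric(within_module_cor) ||
      !(length(within_module_cor) %in% c(1L, max(k, 1L))) ||
      any(within_module_cor <= 0) || any(within_module_cor >= 1))
    fail("within_module_cor", "must lie strictly in (0, 1)")
  if (k > 0) within_module_cor <- rep_len(within_module_cor, k)
  if (!is.numeric(hub_fraction) || hub_fraction < 0 || hub_fraction > 1)
    fail("hub_fraction", "must lie in [0, 1]")
  if (!is.numeric(hub_loading) || hub_loading <= 0)
    fail("hub_loading", "must be positive")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    fail("noise_sd", "must be positive")
  if (!is.numeric(trait_noise_sd) || trait_noise_sd < 0)
    fail("trait_noise_sd", "must be non-negative")
  trait_genes <- as.integer(trait_genes)
  if (length(trait_genes) > 0) {
    if (any(trait_genes < 1 | trait_genes > n_genes))
      fail("trait_genes", "must be gene indices in 1..n_genes")
    module_of <- rep(0L, n_genes)
    if (k > 0)
      module_of[seq_len(sum(module_sizes))] <-
        rep(seq_len(k), times = module_sizes)
    mods <- unique(module_of[trait_genes])
    if (length(mods) != 1 || mods == 0L)
      fail("trait_genes", "must all belong to a single planted module")
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    fail("seed", "must be an integer")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 module_sizes = module_sizes,
                 within_module_cor = within_module_cor,
                 hub_fraction = hub_fraction,
                 hub_loading = hub_loading,
                 trait_genes = trait_genes,
                 trait_effect = trait_effect,
                 trait_noise_sd = trait_noise_sd,
                 noise_sd = noise_sd,
                 baseline_mean = baseline_mean,
                 seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Generate a synthetic log2 expression matrix with planted structure
#'
#' Draws the matrix described by a [synthetic_design()]: module genes from a
#' shared latent factor plus Gaussian noise, background genes as independent
#' noise. Planted metadata travel as attributes: `modules` (integer label per
#' gene, 0 = background), `hubs` (logical per gene), `trait` (per-sample trait
#' vector) and `factors` (the latent factor per module).
#'
#' @param design a `synthetic_design`.
#' @return A genes x samples numeric matrix (log2 scale) with dimnames and the
#'   attributes described above.
#' @examples
#' d <- synthetic_design(100, 40, module_sizes = c(30, 20), seed = 7)
#' x <- generate_expression(d)
#' table(attr(x, "modules"))
#' @export
generate_expression <- function(design) {
  if (!inherits(design, "synthetic_design"))
    stop("design must be created by synthetic_design()", call. = FALSE)
  set.seed(design$seed)
  g <- design$n_genes; s <- design$n_samples
  k <- length(design$module_sizes)
  module_of <- rep(0L, g)
  if (k > 0)
    module_of[seq_len(sum(design$module_sizes))] <-
      rep(seq_len(k), times = design$module_sizes)
  hubs <- rep(FALSE, g)
  factors <- if (k > 0)
    matrix(rnorm(k * s), nrow = k) else matrix(0, 0, s)
  x <- matrix(0, g, s,
              dimnames = list(sprintf("gene%04d", seq_len(g)),
                              sprintf("sample%03d", seq_len(s))))
  for (m in seq_len(k)) {
    idx <- which(module_of == m)
    rho <- design$within_module_cor[m]
    lambda <- design$noise_sd * sqrt(rho / (1 - rho))
    n_hub <- floor(design$hub_fraction * length(idx))
    hubs[idx[seq_len(n_hub)]] <- TRUE
    loading <- ifelse(hubs[idx], design$hub_loading * lambda, lambda)
    x[idx, ] <- loading %o% factors[m, ]
  }
  x <- x + design$baseline_mean +
    matrix(rnorm(g * s, sd = design$noise_sd), g, s)
  trait <- if (length(design$trait_genes) > 0) {
    m <- module_of[design$trait_genes[1]]
    design$trait_effect * factors[m, ] +
      rnorm(s, sd = design$trait_noise_sd)
  } else {
    rnorm(s, sd = design$trait_noise_sd)
  }
  names(trait) <- colnames(x)
  structure(x, modules = setNames(module_of, rownames(x)),
            hubs = setNames(hubs, rownames(x)),
            trait = trait, factors = factors,
            class = c("synthetic_expression", "matrix", "array"))
}

#' Two-group trait/expression validation fixture
#'
#' Simulates a qRT-PCR-style validation experiment: animals in a low and a high
#' trait group, trait values drawn per group from a normal truncated at zero
#' (negative fat percentages are meaningless), slaughter ages uniform on 26-31
#' months, a housekeeping covariate, and normalized expression values in which
#' designated effect genes depend linearly on the trait while the rest are
#' noise around the same baseline.
#'
#' @param n_per_group animals per group (>= 2, otherwise the SEM is undefined).
#' @param group_means,group_sds length-2 numeric: trait mean and SD of the
#'   (low, high) groups. Defaults are the marbling study's group summaries
#'   (means 9.54 and 20.84 % intramuscular fat; SDs back-computed from the
#'   printed SEMs at n = 6).
#' @param n_genes number of expression columns.
#' @param effect_genes indices (into `1:n_genes`) of genes whose expression is
#'   `baseline + effect_slope * trait + noise`.
#' @param effect_slope slope of expression on the trait for effect genes.
#' @param expr_noise_sd residual SD of the normalized expression values.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `animal`, `group` (factor low/high),
#'   `age_months`, `imf_percent`, `housekeeping`, then one column per gene
#'   (`gene01`, ...).
#' @export
generate_validation_fixture <- function(n_per_group = 6,
                                        group_means = c(9.54, 20.84),
                                        group_sds = c(3.32, 3.73),
                                        n_genes = 11,
                                        effect_genes = integer(0),
                                        effect_slope = 0.05,
                                        expr_noise_sd = 0.1,
                                        seed = 1L) {
  if (n_per_group < 2)
    stop("n_per_group must be at least 2 (SEM undefined otherwise)",
         call. = FALSE)
  stopifnot(length(group_means) == 2, length(group_sds) == 2,
            all(group_sds >= 0), n_genes >= 1)
  set.seed(seed)
  n <- 2L * n_per_group
  group <- factor(rep(c("low", "high"), each = n_per_group),
                  levels = c("low", "high"))
  imf <- rnorm(n, mean = rep(group_means, each = n_per_group),
               sd = rep(group_sds, each = n_per_group))
  imf <- pmax(imf, 0)  # truncate: fat content cannot be negative
  age <- runif(n, 26, 31)
  hk <- rnorm(n, mean = 1, sd = 0.1)
  expr <- matrix(rnorm(n * n_genes, mean = 0.4, sd = expr_noise_sd),
                 nrow = n,
                 dimnames = list(NULL, sprintf("gene%02d", seq_len(n_genes))))
  for (gidx in as.integer(effect_genes)) {
    stopifnot(gidx >= 1, gidx <= n_genes)
    expr[, gidx] <- 0.1 + effect_slope * imf + rnorm(n, sd = expr_noise_sd)
  }
  cbind(data.frame(animal = sprintf("animal%02d", seq_len(n)),
                   group = group,
                   age_months = age,
                   imf_percent = imf,
                   housekeeping = hk,
                   stringsAsFactors = FALSE),
        as.data.frame(expr))
}

#' The printed 12-animal marbling fixture
#'
#' The twelve Hanwoo steers used for the qRT-PCR validation, with their printed
#' ids, slaughter ages (months), group labels and intramuscular fat
#' percentages. Six animals per group; low-group IMF values sum to 57.26 and
#' high-group values to 125.08.
#'
#' @return A data.frame with columns `animal`, `group`, `age_months`,
#'   `imf_percent`.
#' @export
table1_fixture <- function() {
  data.frame(
    animal = c("509", "537", "539", "543", "590", "706",
               "508", "582", "603", "648", "652", "685"),
    group = factor(rep(c("low", "high"), each = 6),
                   levels = c("low", "high")),
    age_months = c(26, 27, 26, 27, 27, 28,
                   26, 31, 31, 29, 29, 29),
    imf_percent = c(7.11, 6.02, 11.56, 6.6, 12.6, 13.37,
                    27.97, 18.94, 18.3, 20.78, 17.89, 21.2),
    stringsAsFactors = FALSE)
}

#' Forward simulator for the trait-on-expression regression model
#'
#' Generates data directly under the validation regression model
#' `trait = mu + b_expr * expression + b_age * age + b_hk * housekeeping +
#' noise`, so that the expression coefficient of the fitted model has the
#' generating `b_expr` as its true value. Used for parameter-recovery checks
#' of [trait_regression()]; the two-group fixture generator keeps the reverse
#' generative direction and cannot serve that purpose.
#'
#' @param n sample size.
#' @param b_expr,b_age,b_hk true coefficients.
#' @param mu intercept.
#' @param expr_sd SD of the simulated expression values.
#' @param noise_sd residual SD of the trait.
#' @param seed integer RNG seed.
#' @return A data.frame with columns `animal`, `imf_percent`, `age_months`,
#'   `housekeeping` and `gene01` (the expression column), plus an attribute
#'   `truth` holding the generating coefficients.
#' @export
simulate_trait_regression <- function(n = 100,
                                      b_expr = 2,
                                      b_age = 0.2,
                                      b_hk = 0.5,
                                      mu = 5,
                                      expr_sd = 1,
                                      noise_sd = 0.1,
                                      seed = 1L) {
  stopifnot(n >= 5)
  set.seed(seed)
  expr <- rnorm(n, mean = 0.5, sd = expr_sd)
  age <- runif(n, 26, 31)
  hk <- rnorm(n, mean = 1, sd = 0.1)
  trait <- mu + b_expr * expr + b_age * age + b_hk * hk +
    rnorm(n, sd = noise_sd)
  out <- data.frame(animal = sprintf("animal%03d", seq_len(n)),
                    imf_percent = trait,
                    age_months = age,
                    housekeeping = hk,
                    gene01 = expr,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- c(mu = mu, b_expr = b_expr, b_age = b_age, b_hk = b_hk)
  out
}
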