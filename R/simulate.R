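# run expr under a fixed seed, leaving the caller's RNG state untouched
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Saaty lattice: {1/9 ... 1/2, 1, 2 ... 9}; snap a ratio to the nearest
# lattice point on the log scale
.SAATY <- c(1 / (9:2), 1:9)
.saaty_quantize <- function(r) {
  .SAATY[apply(abs(outer(log(r), log(.SAATY), `-`)), 1L, which.min)]
}

#' Specification of a synthetic expert panel
#'
#' Ground truth for [simulate_panel]: per-sibling-group true weight vectors
#' (each summing to 1), the panel size, and the log-scale judgment noise
#' applied before Saaty quantization.
#'
#' @param true_weights Named list: sibling-group id -> named weight vector
#'   summing to 1 (see [tree_sibling_groups]).
#' @param n_experts Panel size (>= 1); the emulated published panel had 25.
#' @param judgment_noise_sd Standard deviation of the multiplicative
#'   log-normal noise on each judged ratio.
#' @param seed Integer seed; generation is a pure function of it.
#' @return Object of class `panel_spec`.
#' @export
panel_spec <- function(true_weights, n_experts = 25L, judgment_noise_sd = 0.1,
                       seed = 1L) {
  stopifnot(is.list(true_weights), length(true_weights) >= 1L, n_experts >= 1L,
            judgment_noise_sd >= 0)
  for (g in names(true_weights)) {
    w <- true_weights[[g]]
    if (is.null(names(w))) stop("weights in group '", g, "' must be named")
    # published weights are printed to 3 decimals, so allow that slack and
    # renormalize (pairwise ratios are scale-invariant anyway)
    if (abs(sum(w) - 1) > 5e-3)
      stop("weights in group '", g, "' do not sum to 1")
    true_weights[[g]] <- w / sum(w)
  }
  structure(list(true_weights = true_weights, n_experts = as.integer(n_experts),
                 judgment_noise_sd = judgment_noise_sd, seed = as.integer(seed)),
            class = "panel_spec")
}

#' Simulate Saaty comparison matrices from planted weights
#'
#' Each expert judges every pair (i, j) in a sibling group as the true ratio
#' `w_i / w_j` perturbed by log-normal noise and snapped to the nearest Saaty
#' lattice value `{1/9..1/2, 1, 2..9}` on the log scale; reciprocity holds by
#' construction. Deterministic under the spec's seed.
#'
#' @param spec A [panel_spec].
#' @return Named list: group id -> list of `n_experts`
#'   [comparison_matrix] objects.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  .with_seed(spec$seed, {
    lapply(spec$true_weights, function(w) {
      n <- length(w)
      ids <- names(w)
      lapply(seq_len(spec$n_experts), function(e) {
        b <- matrix(1, n, n)
        if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
          r <- (w[i] / w[j]) * exp(stats::rnorm(1L, 0, spec$judgment_noise_sd))
          q <- .saaty_quantize(r)
          b[i, j] <- q
          b[j, i] <- 1 / q
        }
        suppressWarnings(comparison_matrix(b, item_ids = ids))
      })
    })
  })
}

#' Specification of a synthetic Likert respondent cohort
#'
#' Ground truth for [simulate_cohort]: a graded (latent-threshold) response
#' model. Each respondent draws a latent resilience trait (normal, shifted by
#' planted covariate group effects); each item response adds an item intercept
#' and residual noise and is cut at `likert_cutpoints` into the ordinal 1-5
#' ratings. `n_invalid` records are blanked so the published 417-distributed /
#' 70-excluded / 347-valid funnel can be rehearsed end to end.
#'
#' @param n_respondents Cohort size; the emulated survey distributed 417.
#' @param trait_sd SD of the latent resilience trait.
#' @param item_intercept_sd SD of per-item intercepts (item easiness spread).
#' @param resid_sd SD of the residual item noise.
#' @param group_effects Named list: covariate name -> named vector of latent
#'   shifts per level (levels absent from the vector shift by 0), e.g.
#'   `list(exercise_habit = c(stable = 0.5))`.
#' @param n_invalid Number of records to corrupt (blank ratings), caught by
#'   [filter_valid].
#' @param likert_cutpoints Four increasing latent thresholds; defaults place
#'   about (10, 20, 30, 25, 15)% of mass on categories 1-5 at zero trait.
#' @param seed Integer seed; generation is a pure function of it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_respondents = 417L, trait_sd = 1,
                        item_intercept_sd = 0.3, resid_sd = 1,
                        group_effects = list(), n_invalid = 0L,
                        likert_cutpoints = NULL, seed = 1L) {
  stopifnot(n_respondents >= 1L, trait_sd >= 0, item_intercept_sd >= 0,
            resid_sd >= 0, n_invalid >= 0L, n_invalid <= n_respondents)
  if (is.null(likert_cutpoints)) {
    s <- sqrt(trait_sd^2 + item_intercept_sd^2 + resid_sd^2)
    if (s == 0) s <- 1
    likert_cutpoints <- stats::qnorm(c(0.10, 0.30, 0.60, 0.85), sd = s)
  }
  if (any(diff(likert_cutpoints) <= 0))
    stop("likert_cutpoints must be strictly increasing")
  structure(list(n_respondents = as.integer(n_respondents), trait_sd = trait_sd,
                 item_intercept_sd = item_intercept_sd, resid_sd = resid_sd,
                 group_effects = group_effects, n_invalid = as.integer(n_invalid),
                 likert_cutpoints = as.numeric(likert_cutpoints),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# covariate vocabulary and sampling fractions for the emulated survey
.COVARIATE_LEVELS <- list(
  gender          = c(female = 0.7, male = 0.3),
  years_of_work   = c("1-4" = 0.3, "5-10" = 0.3, "11-15" = 0.25, ">15" = 0.15),
  job_nature      = c(clinical = 0.4, nursing = 0.3, public_health = 0.2,
                      administration = 0.1),
  major           = c(clinical_medicine = 0.45,
                      public_health_preventive = 0.25, nursing = 0.3),
  certificates    = c(yes = 0.6, no = 0.4),
  exercise_habit  = c(stable = 0.35, occasional = 0.4, none = 0.25),
  training        = c(yes = 0.65, no = 0.35),
  drill           = c(yes = 0.55, no = 0.45)
)

#' Simulate a Likert respondent cohort
#'
#' @param spec A [cohort_spec].
#' @param tree An [indicator_tree] whose leaves become the rating columns.
#' @return A [response_table] of `n_respondents` rows with covariates
#'   (`meta_*` columns) drawn from the declared vocabulary, ordinal 1-5
#'   ratings, and `n_invalid` blanked records.
#' @export
simulate_cohort <- function(spec, tree) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(tree, "indicator_tree"))
  leaves <- leaf_ids(tree)
  n <- spec$n_respondents
  .with_seed(spec$seed, {
    covs <- lapply(.COVARIATE_LEVELS, function(p)
      sample(names(p), n, replace = TRUE, prob = p))
    shift <- numeric(n)
    for (cv in names(spec$group_effects)) {
      if (!(cv %in% names(.COVARIATE_LEVELS)))
        stop("unknown covariate in group_effects: ", cv)
      eff <- spec$group_effects[[cv]]
      unknown <- setdiff(names(eff), names(.COVARIATE_LEVELS[[cv]]))
      if (length(unknown))
        stop("unknown level(s) for '", cv, "': ", paste(unknown, collapse = ", "))
      hit <- eff[match(covs[[cv]], names(eff))]
      shift <- shift + ifelse(is.na(hit), 0, hit) * spec$trait_sd
    }
    trait <- stats::rnorm(n, shift, spec$trait_sd)
    alpha <- stats::rnorm(length(leaves), 0, spec$item_intercept_sd)
    latent <- outer(trait, alpha, `+`) +
      matrix(stats::rnorm(n * length(leaves), 0, spec$resid_sd),
             n, length(leaves))
    ratings <- matrix(findInterval(latent, spec$likert_cutpoints) + 1L,
                      n, length(leaves), dimnames = list(NULL, leaves))
    if (spec$n_invalid > 0L) {
      bad <- sample.int(n, spec$n_invalid)
      ratings[bad, ] <- NA_integer_
    }
    df <- data.frame(respondent_id = sprintf("r%03d", seq_len(n)),
                     stringsAsFactors = FALSE)
    for (cv in names(covs)) df[[paste0("meta_", cv)]] <- covs[[cv]]
    df <- cbind(df, as.data.frame(ratings))
    response_table(df, leaf_ids = leaves, axis = c(1, 5))
  })
}

#' Simulate a Delphi consultation round
#'
#' Each expert's latent view of the items mixes a common item-quality vector
#' (weight = `concordance`) with independent expert noise (weight =
#' `1 - concordance`), then cuts into 1-5 ordinal importance ratings.
#' `concordance = 1` makes all experts identical (Kendall's W = 1);
#' `concordance = 0` gives independent rankings.
#'
#' @param n_experts Number of experts (>= 2).
#' @param n_items Number of candidate indicators (>= 2).
#' @param concordance Mixing weight in \[0, 1\].
#' @param seed Integer seed.
#' @param round Round number attached to the result.
#' @return A [delphi_round].
#' @export
simulate_delphi <- function(n_experts = 25L, n_items = 40L, concordance = 0.6,
                            seed = 1L, round = 1L) {
  stopifnot(n_experts >= 2L, n_items >= 2L,
            concordance >= 0, concordance <= 1)
  .with_seed(seed, {
    quality <- stats::rnorm(n_items)
    noise <- matrix(stats::rnorm(n_experts * n_items), n_experts, n_items)
    latent <- concordance * matrix(quality, n_experts, n_items, byrow = TRUE) +
      (1 - concordance) * noise
    cuts <- stats::qnorm(c(0.1, 0.3, 0.6, 0.85),
                         sd = sqrt(concordance^2 + (1 - concordance)^2))
    ratings <- matrix(findInterval(latent, cuts) + 1L, n_experts, n_items,
                      dimnames = list(NULL, paste0("item", seq_len(n_items))))
    delphi_round(ratings, round = round)
  })
}

#' Simulate a screening round with a planted keep-set
#'
#' Builds a Delphi round in which a chosen set of items satisfies a screening
#' rule by construction (high consensual importance, low dispersion) and the
#' rest fail it — so the published 116-to-46 screening funnel can be exercised
#' with known ground truth.
#'
#' @param n_experts Number of experts.
#' @param n_items Total items.
#' @param n_keep Items planted to survive [screen_indicators] under `rule`.
#' @param rule The [screening_rule] the planted items must satisfy.
#' @param seed Integer seed.
#' @return List with the [delphi_round] (`round`) and the planted `keep` ids.
#' @export
simulate_screening_round <- function(n_experts = 25L, n_items = 116L,
                                     n_keep = 46L, rule = screening_rule(),
                                     seed = 1L) {
  stopifnot(n_keep <= n_items, n_keep >= 0L)
  .with_seed(seed, {
    ids <- paste0("item", seq_len(n_items))
    keep <- sort(sample(ids, n_keep))
    ratings <- matrix(NA_real_, n_experts, n_items, dimnames = list(NULL, ids))
    for (j in seq_len(n_items)) {
      if (ids[j] %in% keep) {
        # tight consensus at the top of the scale
        ratings[, j] <- sample(4:5, n_experts, replace = TRUE, prob = c(0.3, 0.7))
      } else {
        # low and/or dispersed
        ratings[, j] <- sample(1:5, n_experts, replace = TRUE,
                               prob = c(0.3, 0.3, 0.2, 0.1, 0.1))
      }
    }
    # enforce the planted rule exactly (resample until all planted items pass
    # and all others fail; the distributions above make this converge fast)
    repeat {
      mu <- colMeans(ratings); cv <- apply(ratings, 2L, stats::sd) / mu
      pass <- mu >= rule$min_mean_importance & cv <= rule$max_cv
      wrong <- which(pass != (ids %in% keep))
      if (!length(wrong)) break
      for (j in wrong) {
        ratings[, j] <- if (ids[j] %in% keep)
          sample(4:5, n_experts, replace = TRUE, prob = c(0.2, 0.8))
        else sample(1:5, n_experts, replace = TRUE,
                    prob = c(0.35, 0.3, 0.2, 0.1, 0.05))
      }
    }
    list(round = delphi_round(ratings), keep = keep)
  })
}
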