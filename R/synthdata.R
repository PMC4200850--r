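# Synthetic endpoint-table generator. The default shape mirrors the
# neuroprotection extract the model family was developed on: 3548 assay
# outcomes over 3091 distinct compounds, 37 experimental measures, 493
# assays, 11 organisms and 169 targets, ~22% positive outcomes, and
# condition-level activity priors spanning 0.2-0.95.

#' Configuration for the synthetic-data generator
#'
#' @param n_compounds,n_records Number of distinct molecules and of
#'   endpoint records (a compound can appear in several records).
#' @param n_measures,n_assays,n_organisms,n_targets Vocabulary sizes of
#'   the four condition classes. Condition usage is rank-weighted
#'   (1/rank) so a few conditions dominate, as in real assay extracts.
#' @param model Planted `alma_model` supplying the five generating
#'   coefficients (default: the shipped reference model). The planted
#'   intercept is re-calibrated so the positive rate matches
#'   `target_active_rate`.
#' @param target_active_rate Fraction of positive outcomes the planted
#'   intercept is calibrated to (default 0.22, the positive rate of the
#'   extract the reference model was trained on). `NULL` keeps the
#'   model's own intercept.
#' @param prior_range Range of the per-condition activity priors
#'   (default 0.2-0.95).
#' @param prior_shape Shape of the symmetric Beta distribution the
#'   priors are drawn from within `prior_range` (default 1, uniform;
#'   values below 1 give U-shaped, extreme-heavy draws).
#' @param label_noise Temperature of the Bernoulli label link: labels
#'   are drawn with probability `plogis(score / label_noise)`; 0 gives
#'   the noise-free step function `label = (score > 0)`. The default
#'   0.05 keeps labels nearly deterministic given structure and
#'   context, as in curated assay data.
#' @param affinity_sd_prior,affinity_sd_theta Widths of the Gaussian
#'   kernels coupling a record's condition draw to its latent activity
#'   propensity and to its compound's `theta_5` (chemotype-condition
#'   association). Tighter values give stronger coupling.
#' @param stats_mode `"planted"` (default): each condition value's
#'   moving-average value is planted as `prior * chemotype_center` and
#'   the label-generating features use those planted values, so the
#'   generating model is a stable, non-circular ground truth.
#'   `"running"`: the features use active-set statistics computed from
#'   a provisional prior-driven label draw (one labels -> statistics ->
#'   labels pass); see the package vignette for why this mode's
#'   statistics cannot be re-estimated consistently from the final
#'   labels.
#' @param curation_probs Sampling probabilities of the three curation
#'   levels.
#' @param seed Integer seed; a fixed seed makes the output
#'   byte-identical.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_compounds = 3091L, n_records = 3548L,
                         n_measures = 37L, n_assays = 493L,
                         n_organisms = 11L, n_targets = 169L,
                         model = NULL, target_active_rate = 0.22,
                         prior_range = c(0.2, 0.95), prior_shape = 1,
                         label_noise = 0.05,
                         affinity_sd_prior = 0.04,
                         affinity_sd_theta = 0.3,
                         stats_mode = c("planted", "running"),
                         curation_probs = c(expert = 0.5,
                                            intermediate = 0.3,
                                            autocuration = 0.2),
                         seed = 20140924L) {
  counts <- c(n_compounds, n_records, n_measures, n_assays,
              n_organisms, n_targets)
  if (any(counts < 1L))
    stop(alma_error("all generator counts must be >= 1",
                    class = "alma_domain_error"))
  if (is.null(model)) model <- reference_model()
  stopifnot(inherits(model, "alma_model"),
            length(prior_range) == 2L, prior_range[1] <= prior_range[2],
            label_noise >= 0, prior_shape > 0,
            affinity_sd_prior > 0, affinity_sd_theta > 0,
            is.null(target_active_rate) ||
              (target_active_rate > 0 && target_active_rate < 1))
  structure(list(n_compounds = as.integer(n_compounds),
                 n_records = as.integer(n_records),
                 n_measures = as.integer(n_measures),
                 n_assays = as.integer(n_assays),
                 n_organisms = as.integer(n_organisms),
                 n_targets = as.integer(n_targets),
                 model = model,
                 target_active_rate = target_active_rate,
                 prior_range = prior_range, prior_shape = prior_shape,
                 label_noise = label_noise,
                 affinity_sd_prior = affinity_sd_prior,
                 affinity_sd_theta = affinity_sd_theta,
                 stats_mode = match.arg(stats_mode),
                 curation_probs = curation_probs,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Drug-like ring fragments appended to random heteroatom chains; chains
# use single bonds only, so every generated SMILES is valid.
.ring_frags <- c("C1CCCCC1", "c1ccccc1", "C1CCNCC1", "c1ccncc1",
                 "C1CCOC1", "C1CCSC1", "c1ccsc1", "c1ccoc1")

#' Generate a deterministic set of drug-like molecules
#'
#' Draws random linear chains over C, N, O, S (2-14 heavy atoms,
#' carbon-weighted) and appends zero, one or two ring fragments, giving
#' molecules of roughly 2-26 heavy atoms so the entropy descriptor
#' theta_5 spans about 1-4.7 bits. Deterministic under the config seed.
#'
#' @param config A [synth_config()].
#' @return Data frame with columns `compound_id`, `smiles`.
#' @export
generate_molecules <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- config$n_compounds
  smiles <- vapply(seq_len(n), function(i) {
    m <- sample(2:14, 1L)
    chain <- paste(sample(c("C", "C", "C", "N", "O", "S"), m,
                          replace = TRUE), collapse = "")
    n_rings <- sample(0:2, 1L, prob = c(0.4, 0.4, 0.2))
    paste0(chain,
           paste(sample(.ring_frags, n_rings, replace = TRUE),
                 collapse = ""))
  }, character(1L))
  data.frame(compound_id = sprintf("CPD%05d", seq_len(n)),
             smiles = smiles, stringsAsFactors = FALSE)
}

# Draw a prior-range value from the rescaled symmetric Beta.
.draw_prior <- function(n, config) {
  config$prior_range[1] + diff(config$prior_range) *
    stats::rbeta(n, config$prior_shape, config$prior_shape)
}

#' Generate an endpoint table with planted ground truth
#'
#' Builds `n_records` assay outcomes over the given molecules. Every
#' condition value carries a planted activity prior (drawn within
#' `prior_range`) and a planted chemotype center in `theta_5` space.
#' Each record draws a latent activity propensity and a compound, then
#' draws its condition tuple with rank-based weights coupled to both
#' (so active-prone records land in active-prone conditions and
#' compounds are assayed where their chemotype fits, as in real
#' extracts). The planted linear model scores each record on the
#' moving-average features implied by the planted (or running, see
#' [synth_config()]) condition statistics, the intercept is calibrated
#' to the target positive rate, and labels are drawn through the
#' Bernoulli link.
#'
#' @param config A [synth_config()].
#' @param molecules Data frame from [generate_molecules()] (defaults to
#'   generating them from the config).
#' @return A list with `records` (endpoint table with final labels),
#'   `descriptors` (the theta table used), and `truth`: planted
#'   intercept (after calibration) and coefficients, per-record planted
#'   scores and link probabilities, the generating condition-statistics
#'   table (`stats`, in [condition_stats()] layout), the per-condition
#'   priors and chemotype centers, and the stats mode.
#' @export
generate_endpoints <- function(config, molecules = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(molecules)) molecules <- generate_molecules(config)
  desc <- descriptor_block(molecules, k_max = 5L)
  if (any(!is.na(desc$error)))
    stop(alma_error(sprintf(
      "molecule generation produced unparsable SMILES: %s",
      paste(desc$smiles[!is.na(desc$error)], collapse = ", "))))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed + 1L)
  n <- config$n_records
  theta <- desc$theta5
  classes <- c(sx = "measure", au = "assay_id", ot = "organism",
               te = "target_id")
  sizes <- c(sx = config$n_measures, au = config$n_assays,
             ot = config$n_organisms, te = config$n_targets)
  prefix <- c(sx = "M", au = "A", ot = "O", te = "T")
  vocab <- lapply(names(classes), function(cl)
    sprintf("%s%04d", prefix[[cl]], seq_len(sizes[[cl]])))
  names(vocab) <- names(classes)
  priors <- lapply(vocab, function(v)
    stats::setNames(.draw_prior(length(v), config), v))
  centers <- lapply(vocab, function(v)
    stats::setNames(stats::runif(length(v),
                                 stats::quantile(theta, 0.05),
                                 stats::quantile(theta, 0.95)), v))
  # record-level latents: compound, activity propensity, curation level
  idx <- sample(nrow(molecules), n, replace = TRUE)
  theta_i <- theta[idx]
  propensity <- .draw_prior(n, config)
  pick_conditions <- function(cl) {
    v <- vocab[[cl]]
    base <- 1 / seq_along(v)
    W <- outer(propensity, priors[[cl]],
               function(a, b) stats::dnorm(b, a, config$affinity_sd_prior)) *
      outer(theta_i, centers[[cl]],
            function(a, b) stats::dnorm(b, a, config$affinity_sd_theta))
    W <- sweep(W, 2L, base, `*`) + 1e-12
    v[vapply(seq_len(n), function(i)
      sample.int(length(v), 1L, prob = W[i, ]), integer(1L))]
  }
  records <- data.frame(
    compound_id = molecules$compound_id[idx],
    smiles = molecules$smiles[idx],
    curation_level = sample(names(config$curation_probs), n,
                            replace = TRUE, prob = config$curation_probs),
    measure = pick_conditions("sx"),
    assay_id = pick_conditions("au"),
    organism = pick_conditions("ot"),
    target_id = pick_conditions("te"),
    stringsAsFactors = FALSE)

  if (config$stats_mode == "planted") {
    gen_stats <- do.call(rbind, lapply(names(classes), function(cl) {
      data.frame(condition_class = cl, condition_value = vocab[[cl]],
                 n = NA_integer_, n1 = NA_integer_,
                 p1 = unname(priors[[cl]]),
                 mean_theta5 = unname(centers[[cl]]),
                 ma_value = unname(priors[[cl]] * centers[[cl]]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    # one prior-driven provisional label pass feeds running statistics
    p_rec <- rowMeans(cbind(priors$sx[records$measure],
                            priors$au[records$assay_id],
                            priors$ot[records$organism],
                            priors$te[records$target_id]))
    records$label <- stats::rbinom(n, 1L, p_rec)
    if (length(unique(records$label)) < 2L)
      stop(alma_error("provisional label draw is degenerate",
                      class = "alma_numerical_error"))
    gen_stats <- condition_stats(records, desc)
  }

  feats <- ma_features(records, desc, gen_stats)
  lin <- as.matrix(feats) %*% config$model$coef
  a0 <- config$model$intercept
  if (!is.null(config$target_active_rate)) {
    rate <- config$target_active_rate
    noise <- max(config$label_noise, 1e-3)
    a0 <- stats::uniroot(function(a)
      mean(stats::plogis((a + lin) / noise)) - rate,
      lower = -100, upper = 100, tol = 1e-10)$root
  }
  score <- as.numeric(a0 + lin)
  prob <- if (config$label_noise > 0)
    stats::plogis(score / config$label_noise)
  else as.numeric(score > 0)
  for (attempt in seq_len(5L)) {
    label <- stats::rbinom(n, 1L, prob)
    if (length(unique(label)) >= 2L) break
    warning(sprintf("degenerate label draw (attempt %d); redrawing",
                    attempt))
    label <- NULL
  }
  if (is.null(label))
    stop(alma_error(
      "label generation degenerated to one class in 5 attempts; adjust target_active_rate or label_noise",
      class = "alma_numerical_error"))
  records$label <- label
  # fill realized counts into the generating statistics table
  for (cl in names(classes)) {
    col <- classes[[cl]]
    rows <- gen_stats$condition_class == cl
    cnt <- table(factor(records[[col]],
                        levels = gen_stats$condition_value[rows]))
    cnt1 <- table(factor(records[[col]][records$label == 1L],
                         levels = gen_stats$condition_value[rows]))
    gen_stats$n[rows] <- as.integer(cnt)
    gen_stats$n1[rows] <- as.integer(cnt1)
  }
  list(records = records, descriptors = desc,
       truth = list(intercept = a0, coef = as.list(config$model$coef),
                    label_noise = config$label_noise,
                    stats_mode = config$stats_mode,
                    score = score, prob = prob, stats = gen_stats,
                    priors = lapply(priors, as.list),
                    chemotype_centers = lapply(centers, as.list)))
}
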