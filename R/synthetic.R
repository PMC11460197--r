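#' Design of a synthetic two-set TMT plasma study
#'
#' Builds the parameter object consumed by [simulate_dataset()] and
#' [simulate_reference_brain()]. Defaults emulate a two-cohort plasma
#' case/control study: a discovery set of 18 control + 18 AD samples in
#' three TMT batches and a replication set of 36 control + 49 AD samples in
#' five batches, one pooled global-internal-standard (GIS) channel per
#' batch, base abundances spanning ten orders of magnitude, a minority of
#' proteins with true group effects, covariate and batch effects,
#' abundance-dependent (MNAR) missingness, biomarker traits drawn per
#' diagnosis group, and a latent block (module) correlation structure.
#'
#' @param n_proteins Number of proteins to simulate.
#' @param n_samples_per_set Named list; per set, a named vector
#'   `c(control =, AD =)` of biological sample counts.
#' @param n_batches_per_set Named integer vector of TMT batch counts per set.
#' @param gis_per_batch Pooled GIS channels per batch (>= 1).
#' @param frac_de Fraction of proteins with a nonzero true group effect.
#' @param effect_log2fc `c(mean =, sd =)` of true log2 fold-changes
#'   (AD vs control) for effect proteins.
#' @param base_abundance_log10 Range (log10 units) of base abundances,
#'   drawn log10-uniform; the default spans 10 orders of magnitude.
#' @param batch_log2_sd SD of per-batch, per-protein additive offsets on the
#'   log2 scale (multiplicative on the raw scale).
#' @param biological_log2_sd Between-subject biological SD (log2) per
#'   protein. Pooling averages it away, so GIS channels carry only
#'   technical noise — as a pooled aliquot does.
#' @param noise_log2_sd Residual technical measurement SD on the log2
#'   scale, applied to every channel including GIS.
#' @param covariate_effects Named list of SDs for per-protein covariate
#'   slopes: `age` (log2 per year), `sex` (log2 for male), `race` (log2 for
#'   White).
#' @param mnar_intercept,mnar_slope Logistic missingness parameters: a cell
#'   with raw value x is missing with probability
#'   `plogis(mnar_intercept - mnar_slope * log2(x))`.
#' @param trait_params Per-set, per-group `c(mean, sd)` for the biomarker
#'   traits; see [default_trait_params()].
#' @param trait_coupling Correlation (0..1) between each trait and the
#'   per-subject burden of true effect proteins, within diagnosis group.
#' @param n_modules,module_size,module_purity Latent block parameters:
#'   number of correlated protein blocks, members per block, and the
#'   within-block correlation of the latent component.
#' @param module_sd SD (log2) of the latent module component.
#' @param n_reference_samples Samples in the simulated reference (brain)
#'   cohort used for eigenprotein construction.
#' @param share_controls If `TRUE`, the first 13 controls of set 2 reuse the
#'   subjects (covariates and traits) of set-1 controls, mimicking a
#'   13-sample overlap between cohorts. Default off.
#' @param seed Integer RNG seed; identical designs give bit-identical output.
#'
#' @return A validated list of class `SyntheticDesign`.
#' @export
synthetic_design <- function(n_proteins = 1000,
                             n_samples_per_set = list(
                               set1 = c(control = 18, AD = 18),
                               set2 = c(control = 36, AD = 49)),
                             n_batches_per_set = c(set1 = 3, set2 = 5),
                             gis_per_batch = 1,
                             frac_de = 0.10,
                             effect_log2fc = c(mean = 0, sd = 0.5),
                             base_abundance_log10 = c(3, 13),
                             batch_log2_sd = 0.5,
                             biological_log2_sd = 0.5,
                             noise_log2_sd = 0.1,
                             covariate_effects = list(age = 0.005, sex = 0.05,
                                                      race = 0.02),
                             mnar_intercept = 1.5,
                             mnar_slope = 0.15,
                             trait_params = default_trait_params(),
                             trait_coupling = 0.5,
                             n_modules = 10,
                             module_size = 20,
                             module_purity = 0.9,
                             module_sd = 1.0,
                             n_reference_samples = 60,
                             share_controls = FALSE,
                             seed = 1L) {
  d <- list(n_proteins = as.integer(n_proteins),
            n_samples_per_set = n_samples_per_set,
            n_batches_per_set = n_batches_per_set,
            gis_per_batch = as.integer(gis_per_batch),
            frac_de = frac_de,
            effect_log2fc = effect_log2fc,
            base_abundance_log10 = base_abundance_log10,
            batch_log2_sd = batch_log2_sd,
            biological_log2_sd = biological_log2_sd,
            noise_log2_sd = noise_log2_sd,
            covariate_effects = covariate_effects,
            mnar_intercept = mnar_intercept,
            mnar_slope = mnar_slope,
            trait_params = trait_params,
            trait_coupling = trait_coupling,
            n_modules = as.integer(n_modules),
            module_size = as.integer(module_size),
            module_purity = module_purity,
            module_sd = module_sd,
            n_reference_samples = as.integer(n_reference_samples),
            share_controls = isTRUE(share_controls),
            seed = as.integer(seed))
  validate_design(d)
  structure(d, class = "SyntheticDesign")
}

validate_design <- function(d) {
  if (d$n_proteins < 1) stop("design error: n_proteins must be positive")
  if (!identical(sort(names(d$n_samples_per_set)),
                 sort(names(d$n_batches_per_set))))
    stop("design error: sets in n_samples_per_set and n_batches_per_set differ")
  for (s in names(d$n_samples_per_set)) {
    ns <- d$n_samples_per_set[[s]]
    if (!all(c("control", "AD") %in% names(ns)) || any(ns < 1))
      stop("design error: each set needs positive control and AD counts")
    if (d$n_batches_per_set[[s]] < 1 || d$n_batches_per_set[[s]] > sum(ns))
      stop("design error: batch count must be in [1, n samples] for ", s)
  }
  if (d$gis_per_batch < 1) stop("design error: gis_per_batch must be >= 1")
  if (d$frac_de < 0 || d$frac_de > 1) stop("design error: frac_de outside [0,1]")
  if (d$module_purity <= 0 || d$module_purity > 1)
    stop("design error: module_purity outside (0,1]")
  if (d$module_size < 2 && d$n_modules > 0)
    stop("design error: module_size must be >= 2")
  if (d$n_modules * d$module_size > d$n_proteins)
    stop("design error: n_modules * module_size exceeds n_proteins")
  if (diff(d$base_abundance_log10) < 0)
    stop("design error: base_abundance_log10 range reversed")
  invisible(d)
}

#' Default biomarker trait parameters
#'
#' Per-set, per-group mean (SD) of MoCA, CSF A-beta 1-42, CSF total tau,
#' CSF pTau181 and plasma pTau181 (pg/ml except MoCA), matching published
#' cohort characteristics of a two-set heparin-enriched plasma study.
#' `direction` gives the sign of each trait's coupling to AD effect-protein
#' burden (cognition and CSF A-beta fall with burden, tau species rise).
#'
#' @return A nested list: `params[[set]][[group]][[trait]] = c(mean, sd)`
#'   plus a `direction` element.
#' @export
default_trait_params <- function() {
  list(
    set1 = list(
      control = list(MoCA = c(27.1, 1.6), CSF_Abeta42 = c(552.1, 95.0),
                     CSF_tTau = c(41.8, 18.3), CSF_pTau181 = c(25.4, 9.0),
                     plasma_pTau181 = c(1.7, 0.7)),
      AD = list(MoCA = c(13.1, 7.2), CSF_Abeta42 = c(223.9, 75.0),
                CSF_tTau = c(148.5, 70.0), CSF_pTau181 = c(58.7, 18.2),
                plasma_pTau181 = c(4.8, 2.0))),
    set2 = list(
      control = list(MoCA = c(26.9, 2.0), CSF_Abeta42 = c(499.8, 137.7),
                     CSF_tTau = c(54.9, 26.5), CSF_pTau181 = c(25.4, 9.0),
                     plasma_pTau181 = c(2.4, 1.0)),
      AD = list(MoCA = c(16.5, 6.7), CSF_Abeta42 = c(313.7, 145.6),
                CSF_tTau = c(108.6, 43.3), CSF_pTau181 = c(61.6, 25.6),
                plasma_pTau181 = c(3.8, 1.2))),
    direction = c(MoCA = -1, CSF_Abeta42 = -1, CSF_tTau = 1,
                  CSF_pTau181 = 1, plasma_pTau181 = 1)
  )
}

# demographic draw parameters per set/group (age mean/sd, P(male), P(White),
# P(Black)); remaining race mass goes to "Other"
demographics <- list(
  set1 = list(control = list(age = c(68.6, 9.2), male = 0.611,
                             race = c(White = 0.611, Black = 0.389)),
              AD = list(age = c(65.2, 12.1), male = 0.611,
                        race = c(White = 0.667, Black = 0.278))),
  set2 = list(control = list(age = c(70.4, 8.9), male = 0.306,
                             race = c(White = 0.667, Black = 0.333)),
              AD = list(age = c(66.1, 6.6), male = 0.490,
                        race = c(White = 0.918, Black = 0.082)))
)

#' Simulate a two-set, multi-batch TMT-like plasma dataset
#'
#' Generates raw reporter-style intensities with known ground truth. Each
#' set has its own batches; every batch carries `gis_per_batch` pooled GIS
#' channels whose noise-free value equals the mean of the set's biological
#' channels per protein. Batch effects are protein-specific additive log2
#' offsets, covariate effects are per-protein linear slopes, and a latent
#' block structure correlates module-member proteins across samples.
#' Missingness is imposed by [impose_missingness()].
#'
#' @param design A [synthetic_design()] object.
#' @return A list with `matrix` (raw-scale [abundance_matrix()]),
#'   `metadata` (one row per sample: set, batch, channel, GIS flag,
#'   diagnosis, age, sex, race and the biomarker traits) and `truth`
#'   (true log2 fold-changes, DE flags, module labels, batch offsets,
#'   covariate slopes, missingness probabilities).
#' @export
simulate_dataset <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  validate_design(design)
  set.seed(design$seed)
  d <- design
  p <- d$n_proteins
  prot_ids <- sprintf("P%05d", seq_len(p))
  gene_syms <- sprintf("GENE%d", seq_len(p))

  # ground truth effects
  n_de <- round(d$frac_de * p)
  de <- rep(FALSE, p)
  if (n_de > 0) de[sample.int(p, n_de)] <- TRUE
  true_lfc <- numeric(p)
  true_lfc[de] <- stats::rnorm(sum(de), d$effect_log2fc[["mean"]],
                               d$effect_log2fc[["sd"]])

  base_log2 <- stats::runif(p, d$base_abundance_log10[1],
                            d$base_abundance_log10[2]) * log2(10)

  # latent modules: leading blocks of proteins
  module <- rep("grey", p)
  if (d$n_modules > 0) {
    for (m in seq_len(d$n_modules)) {
      idx <- ((m - 1) * d$module_size + 1):(m * d$module_size)
      module[idx] <- sprintf("M%d", m)
    }
  }

  slopes <- cbind(age = stats::rnorm(p, 0, d$covariate_effects$age),
                  sexMale = stats::rnorm(p, 0, d$covariate_effects$sex),
                  raceWhite = stats::rnorm(p, 0, d$covariate_effects$race))
  rownames(slopes) <- prot_ids

  meta_list <- list()
  clean_cols <- list()    # noise/batch-free log2 signal per sample
  final_cols <- list()
  batch_offsets <- list()
  shared_subjects <- NULL

  for (set_name in names(d$n_samples_per_set)) {
    ns <- d$n_samples_per_set[[set_name]]
    nb <- d$n_batches_per_set[[set_name]]
    groups <- rep(c("control", "AD"), times = ns[c("control", "AD")])
    n_bio <- length(groups)
    sid <- sprintf("%s.s%02d", set_name, seq_len(n_bio))

    # randomized but diagnosis-balanced batch assignment
    batch <- integer(n_bio)
    for (g in c("control", "AD")) {
      gi <- sample(which(groups == g))
      batch[gi] <- rep_len(seq_len(nb), length(gi))
    }

    # demographics and traits per subject
    age <- sex <- race <- numeric(n_bio)
    sex <- race <- character(n_bio)
    for (g in c("control", "AD")) {
      gi <- which(groups == g)
      dm <- demographics[[set_name]][[g]]
      age[gi] <- stats::rnorm(length(gi), dm$age[1], dm$age[2])
      sex[gi] <- ifelse(stats::runif(length(gi)) < dm$male, "Male", "Female")
      race[gi] <- sample(c("White", "Black", "Other"), length(gi),
                         replace = TRUE,
                         prob = c(dm$race["White"], dm$race["Black"],
                                  max(0, 1 - sum(dm$race))))
    }

    # subject-level (batch- and technical-noise-free) log2 signal; this is
    # what pooling sees, so GIS is built from it
    clean <- matrix(base_log2, p, n_bio)
    clean <- clean + outer(true_lfc, as.numeric(groups == "AD"))
    clean <- clean + slopes[, "age"] %o% (age - 65) +
      slopes[, "sexMale"] %o% as.numeric(sex == "Male") +
      slopes[, "raceWhite"] %o% as.numeric(race == "White")
    if (d$n_modules > 0) {
      lam <- sqrt(d$module_purity)
      for (m in seq_len(d$n_modules)) {
        idx <- which(module == sprintf("M%d", m))
        fm <- stats::rnorm(n_bio)         # module-specific factor
        eps <- matrix(stats::rnorm(length(idx) * n_bio), length(idx))
        clean[idx, ] <- clean[idx, ] +
          d$module_sd * (lam * rep(fm, each = length(idx)) +
                           sqrt(1 - d$module_purity) * eps)
      }
    }
    clean <- clean + matrix(stats::rnorm(p * n_bio, 0, d$biological_log2_sd),
                            p, n_bio)
    colnames(clean) <- sid

    # pooled GIS: noise-free value = mean of the set's biological raw values
    gis_clean <- log2(rowMeans(2^clean))

    off <- matrix(stats::rnorm(p * nb, 0, d$batch_log2_sd), p, nb,
                  dimnames = list(prot_ids, sprintf("%s.b%d", set_name,
                                                    seq_len(nb))))
    batch_offsets[[set_name]] <- off

    # assemble biological channels
    sig <- clean + off[, batch] +
      matrix(stats::rnorm(p * n_bio, 0, d$noise_log2_sd), p, n_bio)

    # GIS channels per batch
    gis_ids <- character(0); gis_batch <- integer(0)
    gis_sig <- NULL
    for (b in seq_len(nb)) {
      for (k in seq_len(d$gis_per_batch)) {
        gid <- sprintf("%s.b%d.GIS%d", set_name, b, k)
        col <- gis_clean + off[, b] +
          stats::rnorm(p, 0, d$noise_log2_sd)
        gis_sig <- cbind(gis_sig, col)
        gis_ids <- c(gis_ids, gid); gis_batch <- c(gis_batch, b)
      }
    }
    colnames(gis_sig) <- gis_ids

    # traits, coupled to effect-protein burden within diagnosis group
    burden <- if (any(de)) {
      colSums(sign(true_lfc[de]) * clean[de, , drop = FALSE]) / sum(de)
    } else rep(0, n_bio)
    dirs <- d$trait_params$direction
    traits <- matrix(NA_real_, n_bio, length(dirs),
                     dimnames = list(NULL, names(dirs)))
    rho <- if (any(de)) d$trait_coupling else 0
    for (g in c("control", "AD")) {
      gi <- which(groups == g)
      bz <- burden[gi] - mean(burden[gi])
      if (length(gi) > 1 && isTRUE(stats::sd(bz) > 0)) bz <- bz / stats::sd(bz)
      for (tr in colnames(traits)) {
        pr <- d$trait_params[[set_name]][[g]][[tr]]
        traits[gi, tr] <- pr[1] + pr[2] *
          (rho * dirs[[tr]] * bz +
             sqrt(1 - rho^2) * stats::rnorm(length(gi)))
      }
    }
    traits[, "MoCA"] <- pmin(pmax(traits[, "MoCA"], 0), 30)
    for (tr in setdiff(colnames(traits), "MoCA"))
      traits[, tr] <- pmax(traits[, tr], 0.1)

    meta_bio <- data.frame(
      sample_id = sid, subject_id = sprintf("%s.subj%02d", set_name,
                                            seq_len(n_bio)),
      set = set_name, batch = sprintf("%s.b%d", set_name, batch),
      channel = sprintf("ch%02d", stats::ave(batch, batch, FUN = seq_along)),
      is_gis = FALSE, diagnosis = groups, age = age, sex = sex, race = race,
      stringsAsFactors = FALSE)
    meta_bio <- cbind(meta_bio, as.data.frame(traits))

    # optional 13-control overlap with set 1
    if (d$share_controls && set_name == "set2" && !is.null(shared_subjects)) {
      ctl <- which(meta_bio$diagnosis == "control")
      k <- min(13, length(ctl), nrow(shared_subjects))
      keep <- c("subject_id", "age", "sex", "race",
                names(d$trait_params$direction))
      meta_bio[ctl[seq_len(k)], keep] <- shared_subjects[seq_len(k), keep]
    }
    if (set_name == "set1")
      shared_subjects <- meta_bio[meta_bio$diagnosis == "control", , drop = FALSE]

    meta_gis <- data.frame(
      sample_id = gis_ids, subject_id = NA_character_, set = set_name,
      batch = sprintf("%s.b%d", set_name, gis_batch),
      channel = sprintf("gis%02d", seq_along(gis_ids)),
      is_gis = TRUE, diagnosis = NA_character_,
      age = NA_real_, sex = NA_character_, race = NA_character_,
      stringsAsFactors = FALSE)
    for (tr in colnames(traits)) meta_gis[[tr]] <- NA_real_

    meta_list[[set_name]] <- rbind(meta_bio, meta_gis)
    final_cols[[set_name]] <- cbind(sig, gis_sig)
  }

  log2_all <- do.call(cbind, unname(final_cols))
  rownames(log2_all) <- prot_ids
  raw <- 2^log2_all
  metadata <- do.call(rbind, unname(meta_list))
  rownames(metadata) <- NULL

  mat <- abundance_matrix(raw, gene_syms, scale = "raw")
  truth <- list(true_log2fc = stats::setNames(true_lfc, prot_ids),
                de = stats::setNames(de, prot_ids),
                module = stats::setNames(module, prot_ids),
                batch_offsets = batch_offsets,
                covariate_slopes = slopes,
                miss_prob = NULL)

  mm <- impose_missingness(mat, design)
  truth$miss_prob <- mm$prob
  list(matrix = mm$matrix, metadata = metadata, truth = truth)
}

#' Impose abundance-dependent (MNAR) missingness
#'
#' Each observed cell of a raw-scale matrix is independently set missing
#' with probability `plogis(mnar_intercept - mnar_slope * log2(x))`, so low
#' intensities vanish preferentially, emulating the zero-as-missing
#' convention of reporter-ion quantification where faint signals drop out.
#'
#' @param matrix A raw-scale [abundance_matrix()].
#' @param design A [synthetic_design()] (only the `mnar_*` fields are used).
#' @return A list with `matrix` (cells blanked to `NA`) and `prob` (the
#'   per-cell missingness probabilities).
#' @export
impose_missingness <- function(matrix, design) {
  stopifnot(is_abundance_matrix(matrix), matrix$scale == "raw")
  v <- matrix$values
  prob <- stats::plogis(design$mnar_intercept -
                          design$mnar_slope * log2(v))
  prob[is.na(v)] <- NA_real_
  u <- stats::runif(length(v))
  drop <- !is.na(prob) & u < prob
  v[drop] <- NA_real_
  list(matrix = am_with_values(matrix, v), prob = prob)
}

#' Simulate a reference (brain-like) cohort with known modules
#'
#' Generates a log2-scale reference expression matrix in which the first
#' `n_modules * module_size` proteins form correlated blocks
#' (member = sqrt(purity) * latent factor + sqrt(1-purity) * noise, scaled
#' by `module_sd`) and the remaining proteins are uncorrelated background.
#' Module eigenproteins are computed from the generated matrix itself, and
#' reference-sample traits (CERAD, Braak, MMSE style) are coupled to the
#' first module's latent factor so module-trait association is testable.
#'
#' @param design A [synthetic_design()].
#' @return A list with `matrix` (log2-scale [abundance_matrix()]),
#'   `network` (a [module_network()]), `truth` (true module labels) and
#'   `ref_metadata` (per-reference-sample traits).
#' @export
simulate_reference_brain <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  validate_design(design)
  if (design$module_size < 2) stop("design error: module_size must be >= 2")
  set.seed(derive_seed(design$seed, 77))
  d <- design
  p <- d$n_proteins
  n <- d$n_reference_samples
  prot_ids <- sprintf("P%05d", seq_len(p))
  gene_syms <- sprintf("GENE%d", seq_len(p))
  sid <- sprintf("ref.s%02d", seq_len(n))

  base <- stats::runif(p, d$base_abundance_log10[1],
                       d$base_abundance_log10[2]) * log2(10)
  x <- matrix(base, p, n) +
    matrix(stats::rnorm(p * n, 0, d$noise_log2_sd), p, n)
  module <- rep("grey", p)
  lam <- sqrt(d$module_purity)
  factors <- matrix(stats::rnorm(d$n_modules * n), d$n_modules, n)
  for (m in seq_len(d$n_modules)) {
    idx <- ((m - 1) * d$module_size + 1):(m * d$module_size)
    module[idx] <- sprintf("M%d", m)
    eps <- matrix(stats::rnorm(length(idx) * n), length(idx))
    x[idx, ] <- x[idx, ] +
      d$module_sd * (lam * rep(factors[m, ], each = length(idx)) +
                       sqrt(1 - d$module_purity) * eps)
  }
  dimnames(x) <- list(prot_ids, sid)
  mat <- abundance_matrix(x, gene_syms, scale = "log2")

  members <- split(prot_ids[module != "grey"], module[module != "grey"])
  network <- module_network(mat, members)

  # pathology/cognition-style traits tied to module M1's factor
  f1 <- if (d$n_modules >= 1) factors[1, ] else stats::rnorm(n)
  ref_metadata <- data.frame(
    sample_id = sid,
    CERAD = pmin(pmax(round(1.5 + 0.8 * f1 + stats::rnorm(n, 0, 0.5)), 0), 3),
    Braak = pmin(pmax(round(3 + 1.2 * f1 + stats::rnorm(n, 0, 0.8)), 0), 6),
    MMSE = pmin(pmax(24 - 4 * f1 + stats::rnorm(n, 0, 2), 0), 30),
    stringsAsFactors = FALSE)

  list(matrix = mat, network = network,
       truth = stats::setNames(module, prot_ids),
       ref_metadata = ref_metadata)
}
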