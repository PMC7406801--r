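#' Specification for a synthetic multimodal cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: four
#' diagnostic groups (AD, converting MCI, stable MCI, healthy controls),
#' one feature block per modality, a standardized mean-shift signal on a
#' subset of "affected" regions per modality, and a group-specific latent
#' factor that induces inter-regional correlation (so that group brain
#' graphs differ).
#'
#' @param group_sizes Named integer vector of subjects per diagnostic group.
#' @param block_sizes Named integer vector of features per modality block.
#'   The APOE block must have size 2 (a pair of allele codes).
#' @param effect_size Standardized mean shift delta, in units of the
#'   within-group SD, applied to affected regions (scaled by group severity:
#'   HC 0, MCIs 1/3, MCIc 2/3, AD 1).
#' @param affected_fraction Fraction of regions per modality carrying signal.
#'   Scalar, or named per non-APOE modality (0 makes a modality pure noise).
#' @param overlap Fraction of each modality's affected set shared with the
#'   other modalities; low overlap makes modality information complementary.
#' @param noise_sd Residual standard deviation of every feature.
#' @param covariance_strength Latent-factor loading rho per group (named
#'   vector or scalar); off-diagonal inter-regional correlation is rho^2.
#' @param apoe_allele_probs 4 x 3 matrix of per-group allele probabilities
#'   for alleles (2, 3, 4); rows named by group. The default enriches the
#'   epsilon-4 allele in AD and converting MCI.
#' @param seed Integer seed; identical seeds reproduce the cohort bitwise.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(group_sizes = c(AD = 33L, MCIc = 31L, MCIs = 30L, HC = 35L),
                        block_sizes = c(sMRI = 384L, FDG = 384L, AV45 = 384L,
                                        rsfMRI = 200L, DTI = 50L, APOE = 2L),
                        effect_size = 1.0,
                        affected_fraction = 0.2,
                        overlap = 0.3,
                        noise_sd = 1.0,
                        covariance_strength = c(AD = 0.5, MCIc = 0.4,
                                                MCIs = 0.3, HC = 0.2),
                        apoe_allele_probs = NULL,
                        seed = 1L) {
  if (any(group_sizes <= 0) || any(block_sizes <= 0)) {
    stop("all group and block sizes must be positive")
  }
  stopifnot_scalar_prob(affected_fraction, "affected_fraction")
  stopifnot_scalar_prob(overlap, "overlap")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  if (is.null(names(group_sizes))) stop("'group_sizes' must be named")
  if (is.null(names(block_sizes))) stop("'block_sizes' must be named")
  groups <- names(group_sizes)
  if (is.null(apoe_allele_probs)) {
    apoe_allele_probs <- rbind(
      AD   = c(0.03, 0.57, 0.40),
      MCIc = c(0.04, 0.61, 0.35),
      MCIs = c(0.06, 0.74, 0.20),
      HC   = c(0.08, 0.78, 0.14)
    )
    missing <- setdiff(groups, rownames(apoe_allele_probs))
    if (length(missing)) {
      extra <- matrix(rep(c(0.07, 0.76, 0.17), length(missing)),
                      ncol = 3, byrow = TRUE, dimnames = list(missing, NULL))
      apoe_allele_probs <- rbind(apoe_allele_probs, extra)
    }
    apoe_allele_probs <- apoe_allele_probs[groups, , drop = FALSE]
  }
  rho <- covariance_strength
  if (length(rho) == 1L) rho <- stats::setNames(rep(rho, length(groups)), groups)
  if (!all(groups %in% names(rho))) {
    if (missing(covariance_strength)) {
      # default loadings only name the canonical groups; give others a
      # middling loading rather than failing
      extra <- setdiff(groups, names(rho))
      rho <- c(rho, stats::setNames(rep(0.3, length(extra)), extra))
    } else {
      stop("'covariance_strength' must cover every group")
    }
  }
  stopifnot_scalar_prob(rho, "covariance_strength")
  # Table-1-style demographics, used only for stratified splitting
  demog <- list(
    age_mean = c(AD = 75.65, MCIc = 72.27, MCIs = 72.90, HC = 77.83),
    age_sd   = c(AD = 8.61,  MCIc = 7.40,  MCIs = 7.86,  HC = 6.17),
    p_male   = c(AD = 21 / 33, MCIc = 16 / 31, MCIs = 17 / 30, HC = 14 / 35)
  )
  structure(list(group_sizes = group_sizes, block_sizes = block_sizes,
                 effect_size = effect_size,
                 affected_fraction = affected_fraction, overlap = overlap,
                 noise_sd = noise_sd, covariance_strength = rho[groups],
                 apoe_allele_probs = apoe_allele_probs,
                 demographics = demog, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic multimodal cohort specification\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                          collapse = ", "), "\n")
  cat("  blocks: ", paste(sprintf("%s=%d", names(x$block_sizes), x$block_sizes),
                          collapse = ", "),
      sprintf(" (total %d)\n", sum(x$block_sizes)))
  cat(sprintf("  effect size %.2f SD, affected fraction %s, overlap %.2f, seed %d\n",
              x$effect_size, paste(format(x$affected_fraction), collapse = "/"),
              x$overlap, x$seed))
  invisible(x)
}

# severity multiplier applied to the mean shift, by group
.group_severity <- function(groups) {
  sev <- c(HC = 0, MCIs = 1 / 3, MCIc = 2 / 3, AD = 1)
  out <- sev[groups]
  out[is.na(out)] <- 0.5  # unknown labels get an intermediate severity
  names(out) <- groups
  out
}

.affected_fraction_for <- function(spec, modality) {
  af <- spec$affected_fraction
  if (length(af) == 1L && is.null(names(af))) return(unname(af))
  if (!is.null(names(af)) && modality %in% names(af)) return(unname(af[modality]))
  if (length(af) == 1L) return(unname(af))
  stop(sprintf("no affected_fraction given for modality '%s'", modality))
}

#' Generate a seeded synthetic multimodal cohort
#'
#' Draws per-subject feature blocks for every modality in the specification.
#' Non-APOE blocks are Gaussian with unit-SD noise, a latent factor per group
#' (loading `covariance_strength`, so inter-regional correlation is rho^2)
#' and a mean shift of `effect_size * noise_sd * severity(group)` on the
#' modality's affected regions. Affected sets partially overlap across
#' modalities so that fusion is complementary. The APOE block is a pair of
#' allele codes from \{2, 3, 4\} with the epsilon-4 allele enriched in the
#' AD and converting-MCI groups.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `multimodal_cohort` with elements
#'   `subject_ids`, `labels` (factor), `blocks` (named list of
#'   subjects x features matrices), `apoe` (n x 2 integer matrix),
#'   `covariates` (age, sex; used only for stratified splitting),
#'   `affected` (the ground-truth affected-region indices per modality)
#'   and the originating `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$group_sizes < 2)) {
    stop("every group needs at least 2 subjects (correlation-based graphs are undefined below that)")
  }
  groups <- names(spec$group_sizes)
  labels <- factor(rep(groups, spec$group_sizes), levels = groups)
  n <- length(labels)
  subject_ids <- sprintf("S%03d", seq_len(n))
  sev <- .group_severity(groups)
  blocks <- list()
  affected <- list()
  with_seed(spec$seed, {
    mods <- names(spec$block_sizes)
    non_apoe <- setdiff(mods, "APOE")
    min_p <- min(spec$block_sizes[non_apoe])
    shared_pool <- sample.int(min_p)  # canonical shared ordering of region ids
    for (m in non_apoe) {
      p <- spec$block_sizes[[m]]
      af <- .affected_fraction_for(spec, m)
      k <- if (af > 0) max(1L, floor(af * p)) else 0L
      if (k > 0) {
        n_shared <- floor(spec$overlap * k)
        shared <- shared_pool[seq_len(min(n_shared, k))]
        rest <- sample(setdiff(seq_len(p), shared), k - length(shared))
        aff <- sort(c(shared, rest))
      } else aff <- integer(0)
      affected[[m]] <- aff
      rho <- spec$covariance_strength
      module <- ((seq_len(p) - 1L) %% 4L) + 1L   # 4 region modules, round-robin
      X <- matrix(0, n, p)
      for (g in groups) {
        idx <- which(labels == g)
        ng <- length(idx)
        # global factor with exact unit sample variance: injected
        # inter-regional correlation is rho^2 by construction
        f <- drop(scale(stats::rnorm(ng)))
        # modular factors (loading rho/2, capped to keep the budget PSD)
        # concentrate strong edges within modules so that group graphs
        # differ in topology, not just in level
        m2 <- min((rho[[g]] / 2)^2, (1 - rho[[g]]^2) / 2)
        fm <- scale(matrix(stats::rnorm(ng * 4L), ng, 4L))
        eps <- matrix(stats::rnorm(ng * p), ng, p)
        Xg <- rho[[g]] * f + sqrt(m2) * fm[, module] +
          sqrt(1 - rho[[g]]^2 - m2) * eps
        Xg <- Xg * spec$noise_sd
        if (length(aff)) {
          Xg[, aff] <- Xg[, aff] + spec$effect_size * spec$noise_sd * sev[[g]]
        }
        X[idx, ] <- Xg
      }
      dimnames(X) <- list(subject_ids, sprintf("%s_r%03d", m, seq_len(p)))
      blocks[[m]] <- X
    }
    # APOE: two allele draws per subject, sorted, codes in {2,3,4}
    apoe <- matrix(3L, n, 2L, dimnames = list(subject_ids, c("allele1", "allele2")))
    for (g in groups) {
      idx <- which(labels == g)
      pr <- spec$apoe_allele_probs[g, ]
      a <- matrix(sample(c(2L, 3L, 4L), 2L * length(idx), replace = TRUE, prob = pr),
                  ncol = 2L)
      apoe[idx, ] <- t(apply(a, 1L, sort))
    }
    if ("APOE" %in% mods) {
      if (spec$block_sizes[["APOE"]] != 2L) stop("the APOE block must have size 2")
      blocks[["APOE"]] <- `dimnames<-`(apoe * 1.0,
                                       list(subject_ids, c("APOE_allele1", "APOE_allele2")))
      blocks <- blocks[mods]  # restore spec ordering
    }
    d <- spec$demographics
    gl <- as.character(labels)
    amean <- d$age_mean[gl]; amean[is.na(amean)] <- 74
    asd <- d$age_sd[gl]; asd[is.na(asd)] <- 7
    pmale <- d$p_male[gl]; pmale[is.na(pmale)] <- 0.5
    age <- stats::rnorm(n, amean, asd)
    sex <- ifelse(stats::runif(n) < pmale, "M", "F")
    covariates <- data.frame(subject_id = subject_ids, age = age, sex = sex,
                             stringsAsFactors = FALSE)
  })
  out <- list(subject_ids = subject_ids, labels = labels, blocks = blocks,
              apoe = apoe, covariates = covariates, affected = affected,
              spec = spec)
  class(out) <- "multimodal_cohort"
  out
}

#' @export
print.multimodal_cohort <- function(x, ...) {
  cat(sprintf("Multimodal cohort: %d subjects, %d modality blocks (%d features)\n",
              length(x$subject_ids), length(x$blocks),
              sum(vapply(x$blocks, ncol, 1L))))
  print(table(x$labels))
  invisible(x)
}

#' Concatenate a cohort's blocks into one feature matrix
#'
#' @param cohort A `multimodal_cohort`.
#' @param modalities Which blocks to include (default all, in spec order).
#' @return A subjects x features numeric matrix.
#' @export
concat_features <- function(cohort, modalities = names(cohort$blocks)) {
  do.call(cbind, cohort$blocks[modalities])
}

#' Subset a cohort to selected subjects
#'
#' @param cohort A `multimodal_cohort`.
#' @param idx Subject indices (or logical vector).
#' @return A `multimodal_cohort` restricted, in the given order, to `idx`.
#' @export
subset_cohort <- function(cohort, idx) {
  if (is.logical(idx)) idx <- which(idx)
  cohort$subject_ids <- cohort$subject_ids[idx]
  cohort$labels <- droplevels(cohort$labels[idx])
  cohort$blocks <- lapply(cohort$blocks, function(b) b[idx, , drop = FALSE])
  cohort$apoe <- cohort$apoe[idx, , drop = FALSE]
  cohort$covariates <- cohort$covariates[idx, , drop = FALSE]
  cohort
}

#' Stratified 70:30 train/test split of a cohort
#'
#' Splits subjects into train and test sets, stratifying by diagnostic label,
#' sex and age tercile so that the split preserves the demographic
#' distribution. The per-class training count is `floor(ratio * n + 0.5)`
#' (round half up); within a class the count is allocated to strata
#' proportionally, largest fractional part first.
#'
#' @param cohort A `multimodal_cohort`.
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed controlling the random draws within strata.
#' @return A list of class `cohort_split` with integer vectors `train` and
#'   `test` (subject indices) and the `ratio`/`seed` used.
#' @export
split_cohort <- function(cohort, ratio = 0.7, seed = 1L) {
  stopifnot(inherits(cohort, "multimodal_cohort"), ratio > 0, ratio < 1)
  labs <- cohort$labels
  if (any(table(labs) < 4)) stop("need at least 4 subjects per class to split")
  age <- cohort$covariates$age
  terc <- cut(age, breaks = stats::quantile(age, c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE, labels = FALSE)
  strata <- interaction(labs, cohort$covariates$sex, terc, drop = TRUE)
  if (any(table(strata) < 2)) {
    warning("some label x sex x age strata have a single subject; falling back to class-only stratification")
    strata <- labs
  }
  train <- integer(0)
  with_seed(seed, {
    for (cl in levels(labs)) {
      in_cl <- which(labs == cl)
      target <- round_half_up(ratio * length(in_cl))
      st <- droplevels(strata[in_cl])
      sizes <- table(st)
      raw <- ratio * as.numeric(sizes)
      base <- floor(raw)
      rem <- target - sum(base)
      if (rem > 0) {
        ord <- order(raw - base, decreasing = TRUE)
        base[ord[seq_len(min(rem, length(base)))]] <-
          base[ord[seq_len(min(rem, length(base)))]] + 1L
      } else if (rem < 0) {
        ord <- order(raw - base)
        take <- which(base > 0)[seq_len(min(-rem, sum(base > 0)))]
        base[take] <- base[take] - 1L
      }
      for (s in seq_along(sizes)) {
        members <- in_cl[st == names(sizes)[s]]
        # order by subject id so the draw is invariant to row ordering
        members <- members[order(cohort$subject_ids[members])]
        k <- min(base[s], length(members))
        if (k > 0) train <- c(train, sample(members, k))
      }
    }
  })
  train <- sort(train)
  out <- list(train = train, test = setdiff(seq_along(labs), train),
              ratio = ratio, seed = as.integer(seed))
  class(out) <- "cohort_split"
  out
}

#' Write a cohort to plain-text files
#'
#' One CSV per modality block (`subject_id` plus feature columns), a
#' `labels.csv` and a `covariates.csv`.
#'
#' @param cohort A `multimodal_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (m in names(cohort$blocks)) {
    f <- file.path(dir, paste0(m, ".csv"))
    utils::write.csv(data.frame(subject_id = cohort$subject_ids,
                                cohort$blocks[[m]], check.names = FALSE),
                     f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "labels.csv")
  utils::write.csv(data.frame(subject_id = cohort$subject_ids,
                              label = as.character(cohort$labels)),
                   f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "covariates.csv")
  utils::write.csv(cohort$covariates, f, row.names = FALSE)
  invisible(c(files, f))
}
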