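#' Synthetic cohort specification
#'
#' Describes the study conditions emulated by the synthetic-patient generator:
#' exponential-distance-rule networks over two "hemisphere" clusters, a focal
#' ground-truth epileptogenic zone (EZ), noisy multimodal abnormality maps, a
#' resection area that covers the EZ for seizure-free (SF) patients and misses
#' part of it for nonseizure-free (NSF) patients, and model-generated
#' iEEG-like activation patterns.
#'
#' @param n_patients cohort size (default 34, mirroring the validation
#'   cohort)
#' @param n_roi atlas size per patient (default 90)
#' @param nsf_fraction fraction of NSF patients (default 8/34)
#' @param edr_alpha exponential decay rate of the surrogate connectome
#' @param generating_rho network density of the ground-truth operating point;
#'   default preserves the mean degree of the reference operating density
#'   (see [equivalent_density()])
#' @param generating_gamma recovery probability of the operating point
#' @param ez_size number of ROIs in the (primary) epileptogenic cluster
#' @param modality_miss_rate probability that an available modality misses a
#'   truly epileptogenic region
#' @param false_positive_rate probability that an available modality flags a
#'   healthy region
#' @param electrode_coverage fraction of ROIs sampled by virtual electrodes
#' @param rescale_exponent focality exponent of the seed-probability map
#' @param nsf_mode `"diffuse"` (default): NSF patients carry a second
#'   epileptogenic cluster which the resection area does not cover;
#'   `"mismatch"`: single cluster, resection area misses part of it
#' @param rng_seed integer base seed
#' @return a `cohort_spec`
#' @export
cohort_spec <- function(n_patients = 34, n_roi = 90, nsf_fraction = 8 / 34,
                        edr_alpha = 1, generating_rho = NULL,
                        generating_gamma = 0.3, ez_size = 6,
                        modality_miss_rate = 0.2, false_positive_rate = 0.05,
                        electrode_coverage = 0.5, rescale_exponent = 3,
                        nsf_mode = c("diffuse", "mismatch"), rng_seed = 1) {
  nsf_mode <- match.arg(nsf_mode)
  if (is.null(generating_rho)) generating_rho <- equivalent_density(n_roi)
  stopifnot(n_patients >= 1, n_roi >= 4, ez_size < n_roi,
            nsf_fraction >= 0, nsf_fraction <= 1,
            modality_miss_rate >= 0, modality_miss_rate <= 1,
            false_positive_rate >= 0, false_positive_rate <= 1,
            electrode_coverage > 0, electrode_coverage <= 1)
  structure(list(n_patients = n_patients, n_roi = n_roi,
                 nsf_fraction = nsf_fraction, edr_alpha = edr_alpha,
                 generating_rho = generating_rho,
                 generating_gamma = generating_gamma, ez_size = ez_size,
                 modality_miss_rate = modality_miss_rate,
                 false_positive_rate = false_positive_rate,
                 electrode_coverage = electrode_coverage,
                 rescale_exponent = rescale_exponent, nsf_mode = nsf_mode,
                 rng_seed = rng_seed),
            class = "cohort_spec")
}

# contiguous cluster: the `size` ROIs nearest (Euclidean) to a center ROI
spatial_cluster <- function(coords, center, size, exclude = integer(0)) {
  d <- sqrt(colSums((t(coords) - coords[center, ])^2))
  d[exclude] <- Inf
  order(d)[seq_len(size)]
}

# map ROIs onto <= 34 database regions by clustering their coordinates;
# small atlases get the identity mapping (one region per ROI)
make_projection <- function(coords, n_regions = 34) {
  if (nrow(coords) <= n_regions) return(seq_len(nrow(coords)))
  km <- stats::kmeans(coords, centers = n_regions, nstart = 3, iter.max = 50)
  as.integer(km$cluster)
}

#' Generate one synthetic patient
#'
#' Builds a patient-specific surrogate connectome, a ground-truth
#' epileptogenic zone, a noisy multimodal presurgical record, the derived
#' seed-probability map, and a resection area consistent with the outcome
#' label: SF resection areas cover the full EZ plus a margin; NSF resection
#' areas miss part of it (under the default `"diffuse"` mode the missed part
#' is a second epileptogenic cluster).
#'
#' @param spec a [cohort_spec()]
#' @param outcome `"SF"` or `"NSF"`
#' @param patient_seed integer seed for this patient
#' @return a `synthetic_patient` list: `net` (unthresholded), `coordinates`,
#'   `true_ez`, `primary_ez`, `presurgical`, `seed_map`, `resection_area`,
#'   `projection`, `outcome`, `spec`
#' @export
generate_patient <- function(spec, outcome = c("SF", "NSF"),
                             patient_seed = spec$rng_seed) {
  outcome <- match.arg(outcome)
  seed_state_guard()
  set.seed(as.integer(patient_seed %% .Machine$integer.max))
  n <- spec$n_roi

  coords <- two_cluster_coordinates(n)
  net <- generate_edr_network(n, spec$edr_alpha, coordinates = coords)
  projection <- make_projection(coords)

  center <- sample.int(n, 1)
  primary <- spatial_cluster(coords, center, spec$ez_size)
  true_ez <- primary
  if (outcome == "NSF" && spec$nsf_mode == "diffuse") {
    # second epileptogenic cluster far from the primary one
    d_primary <- sqrt(colSums((t(coords) - colMeans(coords[primary, , drop = FALSE]))^2))
    cand <- setdiff(order(d_primary, decreasing = TRUE)[seq_len(min(10, n))], primary)
    c2 <- cand[sample.int(length(cand), 1)]
    secondary <- spatial_cluster(coords, c2, spec$ez_size, exclude = primary)
    true_ez <- sort(union(primary, secondary))
  }

  true_regions <- unique(projection[true_ez])
  mods <- names(modality_weights())
  avail <- stats::setNames(c(1, 1, 1, stats::rbinom(3, 1, 0.5)), mods)

  seed_map <- NULL
  for (attempt in 1:100) {
    ab <- matrix(0L, 34, 6, dimnames = list(NULL, mods))
    for (m in which(avail == 1)) {
      flag <- stats::rbinom(34, 1, spec$false_positive_rate)
      flag[true_regions] <- stats::rbinom(length(true_regions), 1,
                                          1 - spec$modality_miss_rate)
      ab[seq_len(max(projection)), m] <- flag[seq_len(max(projection))]
    }
    rec <- presurgical_record(ab, avail)
    A <- aggregate_abnormality(rec)
    sm <- build_seed_map(A, projection, spec$rescale_exponent)
    if (max(sm$sp[true_ez]) > 0) { seed_map <- sm; break }
  }
  if (is.null(seed_map))
    stop("could not generate a seedable abnormality map; noise rates too high")

  margin <- stats::rpois(1, 2)
  covered <- if (outcome == "NSF") {
    # the plan is mislocalized: part of the primary cluster is missed (and,
    # in diffuse mode, the whole secondary cluster)
    drop <- sample(primary, max(1, ceiling(spec$ez_size / 2)))
    setdiff(primary, drop)
  } else primary
  ra_center <- covered[1]
  ra <- sort(union(covered,
                   spatial_cluster(coords, ra_center, min(n - 1, length(covered) + margin),
                                   exclude = setdiff(true_ez, covered))))

  structure(list(net = net, coordinates = coords, true_ez = sort(true_ez),
                 primary_ez = sort(primary), presurgical = rec,
                 seed_map = seed_map, resection_area = ra,
                 projection = projection, outcome = outcome, spec = spec),
            class = "synthetic_patient")
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("synthetic_patient (%s): %d ROIs, EZ %d ROIs, RA %d ROIs\n",
              x$outcome, n_roi(x$net), length(x$true_ez),
              length(x$resection_area)))
  invisible(x)
}

#' Generate a model-driven iEEG-like activation pattern
#'
#' Runs one SIR realization from the true epileptogenic zone on the network
#' thresholded at the generating operating point, restricts it to a random
#' electrode-covered ROI subset (sampling biased toward high seed
#' probability), and records the activation order of the infected sampled
#' ROIs. Realizations in which no sampled ROI activates are redrawn (at most
#' `max_attempts`).
#'
#' @param patient a `synthetic_patient`
#' @param spec its [cohort_spec()] (defaults to the patient's)
#' @param max_attempts redraw cap
#' @return an `ieeg_pattern`
#' @export
generate_ieeg_pattern <- function(patient, spec = patient$spec,
                                  max_attempts = 100) {
  net <- threshold_density(patient$net, spec$generating_rho)
  n <- n_roi(net)
  m <- max(1, round(spec$electrode_coverage * n))
  sampled <- sort(sample.int(n, m, prob = 0.2 + patient$seed_map$sp))
  params <- sir_params(spec$generating_gamma, 1,
                       rng_seed = sample.int(.Machine$integer.max, 1))
  for (attempt in seq_len(max_attempts)) {
    real <- simulate_sir(net, patient$true_ez, params, realization = attempt)
    act <- sampled[is.finite(real$activation_step[sampled])]
    if (length(act) > 0) {
      steps <- real$activation_step[act]
      ord <- order(steps)
      return(ieeg_pattern(sampled, act[ord],
                          rank(steps[ord], ties.method = "average")))
    }
  }
  stop("no sampled ROI activated within max_attempts realizations")
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec()]
#' @param with_patterns also attach an iEEG-like pattern to each patient
#' @return list of `synthetic_patient` objects (with `$ieeg` when requested)
#' @export
generate_cohort <- function(spec, with_patterns = FALSE) {
  n_nsf <- round(spec$nsf_fraction * spec$n_patients)
  outcomes <- c(rep("NSF", n_nsf), rep("SF", spec$n_patients - n_nsf))
  seed_state_guard()
  set.seed(as.integer(spec$rng_seed %% .Machine$integer.max))
  outcomes <- sample(outcomes)
  lapply(seq_len(spec$n_patients), function(i) {
    p <- generate_patient(spec, outcomes[i],
                          patient_seed = spec$rng_seed * 1000 + i)
    if (with_patterns) {
      seed_state_guard()
      set.seed(as.integer((spec$rng_seed * 1000 + i) %% .Machine$integer.max))
      p$ieeg <- generate_ieeg_pattern(p, spec)
    }
    p
  })
}

#' Compute the three outcome biomarkers for one patient
#'
#' Thresholds the patient network at the operating density, runs the
#' resection size sweep to locate the optimal resection, and simulates the
#' planned resection area: returns `s_rop` (optimal resection size; censored
#' sweeps score `S_max + 1`), `ov` (overlap of the optimized resection with
#' the resection area), and `dir_ra` (paired normalized decrease in seizure
#' propagation after resecting the resection area).
#'
#' @param patient a `synthetic_patient`
#' @param sizes resection sizes to scan
#' @param n_realizations paired seed/SIR realizations
#' @param config an [sa_config()]
#' @param rng_seed base seed
#' @param delta_target delta-IR threshold defining the optimal resection
#' @return one-row data frame: `s_rop`, `ov`, `dir_ra`, `outcome`, `censored`
#' @export
compute_biomarkers <- function(patient, sizes = 1:20, n_realizations = 300,
                               config = sa_config(), rng_seed = 1,
                               delta_target = 0.90) {
  spec <- patient$spec
  net <- threshold_density(patient$net, spec$generating_rho)
  params <- sir_params(spec$generating_gamma, n_realizations, rng_seed)
  sweep <- resection_size_sweep(net, patient$seed_map, sizes, params,
                                config = config, delta_target = delta_target,
                                early_stop = TRUE)
  censored <- is.null(sweep$r_op)
  if (censored) {
    # no size reached the target decrease. Censored sweeps still carry
    # ordinal information: score the size as S_max + 1 plus the shortfall of
    # the best decrease achieved (scaled so one missing 10% of propagation
    # costs one extra node), and take the overlap from the disconnecting
    # resection (the smallest seed-isolating set, an interchangeable
    # alternative target), falling back to the largest optimized set if even
    # disconnection was not reached.
    shortfall <- max(0, delta_target - max(sweep$table$delta_mean))
    s_rop <- max(sizes) + 1 + 10 * shortfall
    nodes <- if (!is.null(sweep$r_d)) sweep$r_d$nodes
             else sweep$nodes[[length(sweep$nodes)]]
  } else {
    s_rop <- sweep$r_op$size
    nodes <- sweep$r_op$nodes
  }
  ov <- overlap_with_plan(nodes, patient$resection_area)

  seed_state_guard()
  set.seed(as.integer((rng_seed + 7) %% .Machine$integer.max))
  ra_seeds <- replicate(n_realizations, sample_seed(patient$seed_map),
                        simplify = FALSE)
  dra <- delta_ir(net, patient$resection_area, ra_seeds, params)
  data.frame(s_rop = s_rop, ov = ov, dir_ra = dra$mean,
             outcome = patient$outcome, censored = censored)
}

#' Biomarker table for a whole cohort
#'
#' @param cohort list of `synthetic_patient` objects
#' @param ... passed to [compute_biomarkers()]
#' @return a [cohort_table()]
#' @export
cohort_biomarkers <- function(cohort, ...) {
  rows <- lapply(seq_along(cohort), function(i) {
    args <- list(...)
    if (is.null(args$rng_seed)) args$rng_seed <- 1
    args$rng_seed <- args$rng_seed * 100 + i
    do.call(compute_biomarkers, c(list(cohort[[i]]), args))
  })
  df <- do.call(rbind, rows)
  df$patient_id <- seq_along(cohort)
  cohort_table(df)
}
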