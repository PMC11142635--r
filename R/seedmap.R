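#' Default modality relevance weights
#'
#' Relevance of each presurgical modality for localizing the epileptogenic
#' zone: scalp EEG is the least focal (weight 1), MRI/MEG/PET/SPECT
#' intermediate (2), and invasive EEG the most localized (4).
#'
#' @return named numeric vector over the six modalities
#' @export
modality_weights <- function() {
  c(EEG = 1, MRI = 2, MEG = 2, PET = 2, SPECT = 2, iEEG = 4)
}

#' Names of the 34 database regions
#'
#' The presurgical abnormality database describes 17 regions per hemisphere:
#' six frontal, six temporal, two insular, plus central, parietal and
#' occipital.
#'
#' @return character vector of length 34
#' @export
region_names34 <- function() {
  base <- c("fronto-orbital", "frontal-basal", "frontal-parasagittal",
            "frontal-periventricular", "frontal-lateral", "frontal-operculum",
            "hippocampus", "amygdala", "uncus", "temporal-anterior-neocortical",
            "temporal-posterior-neocortical", "gyrus-parahippocampalis",
            "insula-anterior", "insula-posterior", "central", "parietal",
            "occipital")
  c(paste0("L-", base), paste0("R-", base))
}

#' Presurgical multimodal abnormality record
#'
#' @param abnormality `n_region x 6` 0/1 matrix of abnormality flags
#'   (columns EEG, MRI, MEG, PET, SPECT, iEEG in any order matching the
#'   column names)
#' @param availability named 0/1 vector: whether each modality was acquired.
#'   Abnormality flags are only allowed where the modality is available.
#' @param weights modality relevance weights, default [modality_weights()]
#' @return a `presurgical_record`
#' @export
presurgical_record <- function(abnormality,
                               availability = c(EEG = 1, MRI = 1, MEG = 1,
                                                PET = 1, SPECT = 1, iEEG = 1),
                               weights = modality_weights()) {
  abnormality <- as.matrix(abnormality)
  mods <- names(weights)
  if (is.null(colnames(abnormality))) colnames(abnormality) <- mods
  stopifnot(setequal(colnames(abnormality), mods),
            setequal(names(availability), mods))
  abnormality <- abnormality[, mods, drop = FALSE]
  availability <- availability[mods]
  if (!all(abnormality %in% c(0, 1)) || !all(availability %in% c(0, 1)))
    stop("abnormality and availability must be 0/1")
  bad <- colSums(abnormality)[availability == 0]
  if (any(bad > 0)) stop("abnormality flagged in an unavailable modality")
  structure(list(abnormality = abnormality, availability = availability,
                 weights = weights),
            class = "presurgical_record")
}

#' Aggregate modality flags into an overall abnormality map
#'
#' `A_i = (1/n) * sum_m D_m * w_m * a_im` with `n = sum_m D_m * w_m`, so a
#' region flagged by every available modality has `A_i = 1` and rescaling all
#' modality weights by a constant leaves the map unchanged.
#'
#' @param rec a [presurgical_record()]
#' @return numeric vector `A` over regions, in `[0, 1]`
#' @export
aggregate_abnormality <- function(rec) {
  d <- rec$availability
  w <- rec$weights
  n <- sum(d * w)
  if (n == 0) stop("no presurgical modality available")
  as.numeric(rec$abnormality %*% (d * w)) / n
}

#' Build a seed-probability map
#'
#' Projects the per-region abnormality values onto atlas ROIs through the
#' projection table and applies the focality rescaling `SP_i = A^R`: raising
#' the broad region-level abnormality to a power `R > 1` concentrates seeding
#' probability on regions flagged by several co-occurring modalities without
#' changing their ranking.
#'
#' @param A per-region abnormality values in `[0, 1]`
#' @param projection integer vector mapping each atlas ROI to one database
#'   region (index into `A`)
#' @param R rescaling exponent (>= 1), default 3
#' @return a `seed_probability_map` with fields `sp`, `rescale_exponent`,
#'   `source_abnormality`, `projection`
#' @export
build_seed_map <- function(A, projection, R = 3) {
  if (R < 1) stop("R must be >= 1")
  if (any(A < 0 | A > 1)) stop("abnormality values must lie in [0, 1]")
  projection <- as.integer(projection)
  if (anyNA(projection) || any(projection < 1 | projection > length(A)))
    stop("projection maps an atlas ROI to a missing database region")
  structure(list(sp = A[projection]^R, rescale_exponent = R,
                 source_abnormality = A, projection = projection),
            class = "seed_probability_map")
}

#' @export
print.seed_probability_map <- function(x, ...) {
  cat(sprintf("seed_probability_map: %d ROIs, R = %g, %d with SP > 0 (max %.3f)\n",
              length(x$sp), x$rescale_exponent, sum(x$sp > 0), max(x$sp)))
  invisible(x)
}

#' Sample a seed realization from a seed-probability map
#'
#' Default Bernoulli mode includes each ROI independently with probability
#' `SP_i`, redrawing until the seed is nonempty (at most `max_attempts`
#' draws); `fixed_size` draws `k` distinct ROIs with probability proportional
#' to `SP`. Uses R's RNG (seed with `set.seed()` for reproducibility).
#'
#' @param map a `seed_probability_map`
#' @param mode `"bernoulli"` or `"fixed_size"`
#' @param k seed size for `fixed_size` mode
#' @param max_attempts redraw cap for the Bernoulli mode
#' @return integer vector of seed ROI indices
#' @export
sample_seed <- function(map, mode = c("bernoulli", "fixed_size"), k = NULL,
                        max_attempts = 1000) {
  mode <- match.arg(mode)
  sp <- map$sp
  if (all(sp <= 0)) stop("seed-probability map is identically zero")
  if (mode == "bernoulli") {
    for (a in seq_len(max_attempts)) {
      seed <- which(stats::runif(length(sp)) < sp)
      if (length(seed) > 0) return(seed)
    }
    stop("failed to draw a nonempty seed within max_attempts")
  }
  if (is.null(k) || k < 1 || k > sum(sp > 0))
    stop("fixed_size mode needs 1 <= k <= number of ROIs with SP > 0")
  sort(sample(seq_along(sp), k, prob = sp))
}

#' Read a projection table
#'
#' CSV with columns `atlas_roi` (1-based ROI index) and `database_region`
#' (1-based region index); every atlas ROI must appear exactly once.
#'
#' @param path file path
#' @param n_roi expected number of atlas ROIs (optional check)
#' @return integer projection vector ordered by atlas ROI
#' @export
read_projection <- function(path, n_roi = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("atlas_roi", "database_region") %in% names(df)))
  df <- df[order(df$atlas_roi), ]
  if (anyDuplicated(df$atlas_roi) || !identical(as.integer(df$atlas_roi),
                                                seq_len(nrow(df))))
    stop("projection must map every atlas ROI exactly once")
  if (!is.null(n_roi) && nrow(df) != n_roi)
    stop("projection size does not match the atlas")
  as.integer(df$database_region)
}

#' Write a seed map as CSV (`roi,sp`)
#' @param map a `seed_probability_map`
#' @param path file path
#' @export
write_seed_map <- function(map, path) {
  utils::write.csv(data.frame(roi = seq_along(map$sp), sp = map$sp), path,
                   row.names = FALSE)
  invisible(path)
}
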