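#' Detection noise model
#'
#' Describes an imperfect lesion detector: a per-lesion miss rate, a
#' per-field false-positive rate (Poisson count), Gaussian centre jitter,
#' a type-confusion matrix (rows = true type 1-4, columns = reported
#' type, rows summing to 1), and an optional confidence spread for hits.
#' With everything zero/identity the oracle detector reproduces ground
#' truth exactly.
#'
#' @param miss_rate probability a true lesion is missed (in every field).
#' @param fp_rate expected false positives per field.
#' @param jitter_sd sd of the box-centre jitter in px.
#' @param type_confusion 4 x 4 row-stochastic matrix.
#' @param conf_spread hit confidence is `1 - conf_spread * U(0,1)`.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(miss_rate = 0, fp_rate = 0, jitter_sd = 0,
                        type_confusion = diag(4), conf_spread = 0) {
  type_confusion <- as.matrix(type_confusion)
  stopifnot(all(dim(type_confusion) == 4), all(type_confusion >= 0),
            miss_rate >= 0, miss_rate <= 1, fp_rate >= 0, jitter_sd >= 0,
            conf_spread >= 0, conf_spread <= 1)
  if (any(abs(rowSums(type_confusion) - 1) > 1e-8))
    stop("type_confusion rows must sum to 1")
  structure(list(miss_rate = miss_rate, fp_rate = fp_rate,
                 jitter_sd = jitter_sd, type_confusion = type_confusion,
                 conf_spread = conf_spread), class = "noise_model")
}

# Adjacent-type confusion: mass `p` split to the neighbouring stages.
#' @rdname noise_model
#' @param p total probability mass moved to adjacent types.
#' @export
adjacent_confusion <- function(p) {
  m <- diag(4) * (1 - p)
  m[1, 2] <- p; m[4, 3] <- p
  m[2, 1] <- p / 2; m[2, 3] <- p / 2
  m[3, 2] <- p / 2; m[3, 4] <- p / 2
  m
}

#' Simulated lesion detector with a controllable noise model
#'
#' Stands in for a trained object detector.  Noise is applied
#' independently per lesion (a missed or type-confused lesion is missed
#' or confused consistently across the fields that see it); centre
#' jitter is drawn per field occurrence; false positives are drawn per
#' field.  All random draws happen in a fixed order regardless of the
#' rates, so runs with the same seed and different rates are coupled by
#' common random numbers (a lesion missed at rate 0.2 is also missed at
#' rate 0.4).
#'
#' @param eye a `ground_truth_eye`.
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param plan camera plan; defaults to the eye's own.
#' @return Data frame of detections: `field_id`, `type`, `x0`, `y0`,
#'   `x1`, `y1` (field px), `confidence`, `src_lesion` (`NA` for false
#'   positives).
#' @export
oracle_detector <- function(eye, noise = noise_model(), seed = eye$seed,
                            plan = eye$plan) {
  stopifnot(inherits(noise, "noise_model"))
  gt <- field_ground_truth(eye, plan)
  with_seed(derive_seed(seed, 17), {
    les <- eye$lesions
    n <- nrow(les)
    u_miss <- stats::runif(max(n, 1))
    u_type <- stats::runif(max(n, 1))
    u_conf <- stats::runif(max(n, 1))
    rep_type <- integer(n)
    for (j in seq_len(n)) {
      cum <- cumsum(noise$type_confusion[les$type[j], ])
      rep_type[j] <- which(u_type[j] <= cum + 1e-12)[1]
    }
    dets <- list()
    if (nrow(gt) > 0) {
      jit <- matrix(stats::rnorm(2 * nrow(gt), 0, max(noise$jitter_sd, 1e-12)),
                    ncol = 2)
      if (noise$jitter_sd == 0) jit[] <- 0
      for (k in seq_len(nrow(gt))) {
        j <- match(gt$lesion_id[k], les$lesion_id)
        if (u_miss[j] < noise$miss_rate) next
        dets[[length(dets) + 1]] <- data.frame(
          field_id = gt$field_id[k], type = rep_type[j],
          x0 = gt$x0[k] + jit[k, 1], y0 = gt$y0[k] + jit[k, 2],
          x1 = gt$x1[k] + jit[k, 1], y1 = gt$y1[k] + jit[k, 2],
          confidence = 1 - noise$conf_spread * u_conf[j],
          src_lesion = gt$lesion_id[k], stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(nrow(plan))) {
      nfp <- stats::rpois(1, noise$fp_rate)
      for (q in seq_len(nfp)) {
        w <- stats::runif(1, 20, 60); h <- stats::runif(1, 20, 60)
        x <- stats::runif(1, 0, plan$width[i] - w)
        y <- stats::runif(1, 0, plan$height[i] - h)
        dets[[length(dets) + 1]] <- data.frame(
          field_id = plan$field_id[i], type = sample(1:4, 1),
          x0 = x, y0 = y, x1 = x + w, y1 = y + h,
          confidence = stats::runif(1, 0.2, 0.8),
          src_lesion = NA_character_, stringsAsFactors = FALSE)
      }
    }
    if (length(dets)) do.call(rbind, dets) else
      data.frame(field_id = character(), type = integer(), x0 = numeric(),
                 y0 = numeric(), x1 = numeric(), y1 = numeric(),
                 confidence = numeric(), src_lesion = character(),
                 stringsAsFactors = FALSE)
  })
}
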