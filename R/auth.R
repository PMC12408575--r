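## Enrollment, Mahalanobis verification and closed-set identification.
##
## Each registered subject is represented by the mean (cluster center) and
## per-dimension variance of their training-beat latent means. Verification
## accepts a probe beat when its Mahalanobis distance to the claimed
## subject's center is strictly below the subject's threshold; identification
## assigns the nearest center. Decisions from five consecutive beats are
## combined by 3-of-5 majority voting.

#' Enroll subjects from latent means
#'
#' Per subject: center = per-dimension mean, diagonal covariance =
#' per-dimension sample variance (n-1 convention) floored at `epsilon`. A
#' diagonal covariance is used because the latent dimension typically
#' exceeds the number of enrollment beats, making a full covariance
#' singular.
#'
#' @param latents named list: subject id -> matrix of latent means (rows =
#'   enrollment beats, >= 2 per subject).
#' @param epsilon variance floor (default 1e-6).
#' @return object of class `subject_gallery`.
#' @export
enroll <- function(latents, epsilon = 1e-6) {
  if (!length(latents)) stop_beat("no subjects to enroll")
  if (is.null(names(latents)) || any(names(latents) == ""))
    stop_beat("latents must be a named list (names = subject ids)")
  subjects <- lapply(names(latents), function(id) {
    z <- latents[[id]]
    if (is.null(dim(z)) || nrow(z) < 2L)
      stop_beat("subject %s has fewer than 2 enrollment points", id)
    list(center = colMeans(z),
         variance = pmax(apply(z, 2L, stats::var), epsilon),
         n_enrolled = nrow(z), threshold = NA_real_)
  })
  names(subjects) <- names(latents)
  structure(list(subjects = subjects, epsilon = epsilon,
                 latent_dim = ncol(latents[[1]])),
            class = "subject_gallery")
}

#' @export
print.subject_gallery <- function(x, ...) {
  cat(sprintf("<subject_gallery> %d subject(s), latent dim %d\n",
              length(x$subjects), x$latent_dim))
  for (id in names(x$subjects))
    cat(sprintf("  %s: n = %d, threshold = %s\n", id, x$subjects[[id]]$n_enrolled,
                format(x$subjects[[id]]$threshold, digits = 4)))
  invisible(x)
}

#' Set a subject's verification threshold
#' @param gallery a `subject_gallery`.
#' @param subject_id subject to update.
#' @param threshold Mahalanobis distance threshold.
#' @return the updated gallery.
#' @export
set_threshold <- function(gallery, subject_id, threshold) {
  id <- as.character(subject_id)
  if (is.null(gallery$subjects[[id]])) stop_beat("subject %s not enrolled", id)
  gallery$subjects[[id]]$threshold <- threshold
  gallery
}

#' Diagonal Mahalanobis distance to a subject's cluster center
#'
#' `sqrt(sum_d (z_d - center_d)^2 / var_d)`.
#'
#' @param z latent vector or matrix (rows = probes).
#' @param gallery a `subject_gallery`.
#' @param subject_id enrolled subject id.
#' @return distance (vector when `z` is a matrix).
#' @export
mahalanobis_dist <- function(z, gallery, subject_id) {
  e <- gallery$subjects[[as.character(subject_id)]]
  if (is.null(e)) stop_beat("subject %s not enrolled", subject_id)
  if (is.null(dim(z))) z <- rbind(z)
  unname(sqrt(colSums((t(z) - e$center)^2 / e$variance)))
}

#' Verify a single beat against a claimed identity
#'
#' Accepts iff the Mahalanobis distance is strictly smaller than the claimed
#' subject's threshold (a distance exactly equal to the threshold is
#' rejected).
#'
#' @param z latent vector.
#' @param claimed_id claimed subject id.
#' @param gallery a `subject_gallery` with the claimed subject's threshold set.
#' @return list with `accept` (logical) and `distance`.
#' @export
verify_beat <- function(z, claimed_id, gallery) {
  e <- gallery$subjects[[as.character(claimed_id)]]
  if (is.null(e)) stop_beat("subject %s not enrolled", claimed_id)
  if (is.na(e$threshold)) stop_beat("no threshold set for subject %s", claimed_id)
  d <- mahalanobis_dist(z, gallery, claimed_id)
  list(accept = d < e$threshold, distance = d)
}

#' Verify five consecutive beats with majority voting
#'
#' Per-beat verification followed by a 3-of-5 vote.
#'
#' @param z matrix of exactly 5 latent rows (consecutive beats).
#' @param claimed_id claimed subject id.
#' @param gallery a `subject_gallery`.
#' @return object of class `auth_outcome` with per-beat distances and
#'   decisions, `votes_for` and the final `accept`.
#' @export
verify_voted <- function(z, claimed_id, gallery) {
  if (is.null(dim(z)) || nrow(z) != 5L)
    stop_beat("majority voting requires exactly 5 beats (got %s)",
              if (is.null(dim(z))) 1 else nrow(z))
  d <- mahalanobis_dist(z, gallery, claimed_id)
  thr <- gallery$subjects[[as.character(claimed_id)]]$threshold
  if (is.na(thr)) stop_beat("no threshold set for subject %s", claimed_id)
  dec <- d < thr
  structure(list(claimed_id = claimed_id, distances = d, decisions = dec,
                 votes_for = sum(dec), accept = sum(dec) >= 3L),
            class = "auth_outcome")
}

#' @export
print.auth_outcome <- function(x, ...) {
  cat(sprintf("<auth_outcome> claim %s: %s (%d/5 votes; distances %s)\n",
              x$claimed_id, if (x$accept) "ACCEPT" else "REJECT", x$votes_for,
              paste(sprintf("%.2f", x$distances), collapse = ", ")))
  invisible(x)
}

#' Identify the closest enrolled subject for one beat
#'
#' Argmin of the Mahalanobis distance over the gallery; distance ties break
#' toward the lowest subject id.
#'
#' @param z latent vector.
#' @param gallery a non-empty `subject_gallery`.
#' @return the winning subject id (character).
#' @export
identify_beat <- function(z, gallery) {
  ids <- names(gallery$subjects)
  ids <- ids[order(suppressWarnings(as.numeric(ids)), ids)]
  d <- vapply(ids, function(id) mahalanobis_dist(z, gallery, id), 0)
  ids[which.min(d)]
}

#' Identify from five consecutive beats by majority vote
#'
#' Mode of the per-beat identifications; a tie between modes goes to the
#' tied subject with the smallest mean distance over the five beats, and any
#' remaining tie to the lowest id.
#'
#' @param z matrix of exactly 5 latent rows.
#' @param gallery a `subject_gallery`.
#' @return the winning subject id (character).
#' @export
identify_voted <- function(z, gallery) {
  if (is.null(dim(z)) || nrow(z) != 5L)
    stop_beat("majority voting requires exactly 5 beats")
  per_beat <- apply(z, 1L, identify_beat, gallery = gallery)
  tab <- table(per_beat)
  modes <- names(tab)[tab == max(tab)]
  if (length(modes) == 1L) return(modes)
  md <- vapply(modes, function(id) mean(mahalanobis_dist(z, gallery, id)), 0)
  best <- modes[md == min(md)]
  best[order(suppressWarnings(as.numeric(best)), best)][1]
}
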