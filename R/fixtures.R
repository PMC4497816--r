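# ---------------------------------------------------------------------------
# Synthetic mappings with known ground truth, so every analysis operation is
# testable without running a model.
# ---------------------------------------------------------------------------

# canonical transfer retina -> SC (the ideal biological orientation):
# temporal maps to anterior (AP = 1 - NT) and ventral to medial
# (ML = extent * (1 - DV)); returns target coordinates in SC units
.canonical_transfer <- function(rx, ry, ml_extent) {
  cbind(x = 1 - rx, y = ml_extent * (1 - ry))
}

# nearest SC neuron to each target coordinate
.nearest_sc <- function(tx, ty, substrate) {
  vapply(seq_along(tx), function(q)
    which.min((substrate$sc$x - tx[q])^2 + (substrate$sc$y - ty[q])^2),
    integer(1))
}

#' Construct a synthetic point mapping with known ground truth
#'
#' Kinds:
#' \describe{
#'   \item{identity}{each RGC maps to the SC neuron nearest its canonical
#'     (ideal-orientation) transfer position.}
#'   \item{noisy}{identity plus isotropic Gaussian jitter of SD `noise` on
#'     the target position before snapping to the nearest SC neuron.}
#'   \item{mirrored}{the AP axis of the target is flipped (`AP -> 1 - AP`),
#'     violating AP orientation without introducing edge crossings.}
#'   \item{duplicated}{two interleaved populations (a Bernoulli(0.5) or
#'     Isl2-based split) form two full maps offset along AP by `offset`
#'     (the flagged population shifted anteriorly).}
#'   \item{merged_at}{like `duplicated` nasal of `merge_at`, with the
#'     separation shrinking linearly to zero at `merge_at` and a single map
#'     temporal of it.}
#'   \item{random}{SC targets are a random permutation of the identity
#'     targets.}
#'   \item{half_coverage}{the AP target coordinate is compressed into the
#'     anterior half of the SC.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param substrate the substrate providing the two point sets.
#' @param noise jitter SD for `noisy`.
#' @param offset AP separation of the duplicated maps (SC units).
#' @param merge_at NT position (0-1) where the duplicated maps merge.
#' @param use_isl2 split the duplicated population by the substrate's Isl2
#'   flags instead of a random split.
#' @param seed RNG seed (jitter, permutation, population split).
#' @param with_W also build the consistent one-synapse-per-RGC weight
#'   matrix and return it as attribute `W`.
#' @return a `point_mapping` (as from [strongest_mapping()]).
#' @export
make_mapping <- function(kind = c("identity", "noisy", "mirrored",
                                  "duplicated", "merged_at", "random",
                                  "half_coverage"),
                         substrate, noise = 0.02, offset = 0.5,
                         merge_at = 0.7, use_isl2 = FALSE, seed = 1,
                         with_W = FALSE) {
  kind <- match.arg(kind)
  set.seed(seed)
  r <- substrate$retina
  ml <- substrate$ml_extent
  tgt <- .canonical_transfer(r$x, r$y, ml)
  flag <- rep(FALSE, substrate$n_r)
  if (kind %in% c("duplicated", "merged_at")) {
    flag <- if (use_isl2) r$isl2 else runif(substrate$n_r) < 0.5
  }
  tx <- tgt[, 1]; ty <- tgt[, 2]
  if (kind == "noisy") {
    tx <- tx + rnorm(length(tx), 0, noise)
    ty <- ty + rnorm(length(ty), 0, noise)
  } else if (kind == "mirrored") {
    tx <- 1 - tx
  } else if (kind == "duplicated") {
    # flagged population anterior, other posterior; both full maps
    tx <- tx * (1 - offset) + ifelse(flag, 0, offset)
  } else if (kind == "merged_at") {
    # two separated AP bands nasal of the merge point (the flagged
    # population compressed anteriorly), one band temporal of it
    dup <- flag & r$x < merge_at
    tx <- ifelse(dup, tx * (1 - offset), tx)
  } else if (kind == "random") {
    perm <- sample.int(length(tx))
    tx <- tx[perm]; ty <- ty[perm]
  } else if (kind == "half_coverage") {
    tx <- tx * 0.5
  }
  j <- .nearest_sc(tx, ty, substrate)
  out <- data.frame(i = seq_len(substrate$n_r),
                    rx = r$x, ry = r$y,
                    sx = substrate$sc$x[j], sy = substrate$sc$y[j],
                    j = j, isl2 = flag)
  attr(out, "n_unmapped") <- 0L
  attr(out, "ml_extent") <- ml
  class(out) <- c("point_mapping", "data.frame")
  if (with_W) {
    attr(out, "W") <- Matrix::sparseMatrix(i = out$i, j = out$j, x = 1,
                                           dims = c(substrate$n_r,
                                                    substrate$n_sc))
  }
  out
}
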