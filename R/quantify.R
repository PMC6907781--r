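#' ROI metabolite ratios from reconstructed maps
#'
#' Computes Lac/Pyr, Bic/Pyr, Lac/Bic and the fractional ratios
#' Lac/Total and Bic/Total (Total = Pyr + Lac + Bic) over a region of
#' interest. The default mode ("sum") forms each ratio from the ROI sums
#' of the numerator and denominator maps, which is robust to low-signal
#' voxels; mode "mean" averages per-voxel ratios instead, masking voxels
#' whose denominator falls below the floor.
#'
#' @param maps a [MetaboliteMapSet-class] containing pyr, lac, bic
#' @param mask logical matrix aligned to the map grid
#' @param mode "sum" (ratio of ROI sums, default) or "mean" (mean of
#'   voxel ratios)
#' @param floorFrac denominator floor as a fraction of that map's
#'   maximum; sums (or voxels) below it yield NA
#' @return a [RatioSet-class]
#' @export
roiRatios <- function(maps, mask, mode = c("sum", "mean"),
                      floorFrac = 1e-3) {
  stopifnot(is(maps, "MetaboliteMapSet"))
  mode <- match.arg(mode)
  if (!is.logical(mask) ||
      !all(dim(mask) == dim(maps@maps)[1:2]))
    stop("mask must be a logical matrix aligned to the maps")
  if (!any(mask)) stop("empty-roi: mask has no voxels")
  P <- getMap(maps, "pyr"); L <- getMap(maps, "lac")
  B <- getMap(maps, "bic")
  floorP <- floorFrac * max(P); floorL <- floorFrac * max(L)
  floorB <- floorFrac * max(B)
  nVox <- sum(mask)
  if (mode == "sum") {
    sP <- sum(P[mask]); sL <- sum(L[mask]); sB <- sum(B[mask])
    rat <- function(num, den, fl) if (den / nVox >= fl) num / den
                                  else NA_real_
    tot <- sP + sL + sB
    rs <- new("RatioSet",
              lacPyr = rat(sL, sP, floorP), bicPyr = rat(sB, sP, floorP),
              lacBic = rat(sL, sB, floorB),
              lacTotal = rat(sL, tot, floorP),
              bicTotal = rat(sB, tot, floorP),
              nVoxels = as.integer(nVox), nMasked = 0L, mode = mode)
  } else {
    mrat <- function(num, den, fl) {
      ok <- mask & den >= fl
      list(v = if (any(ok)) mean(num[ok] / den[ok]) else NA_real_,
           masked = sum(mask & !ok))
    }
    tot <- P + L + B
    lp <- mrat(L, P, floorP); bp <- mrat(B, P, floorP)
    lb <- mrat(L, B, floorB); lt <- mrat(L, tot, floorP)
    bt <- mrat(B, tot, floorP)
    rs <- new("RatioSet", lacPyr = lp$v, bicPyr = bp$v, lacBic = lb$v,
              lacTotal = lt$v, bicTotal = bt$v,
              nVoxels = as.integer(nVox),
              nMasked = as.integer(max(lp$masked, bp$masked, lb$masked)),
              mode = mode)
  }
  rs
}

#' Classify the 48-hour Lac/Bic response direction
#'
#' Sign of (post - pre) tumour Lac/Bic: an increase marks a predicted
#' non-responder (test positive for death), a decrease a predicted
#' responder. Exact equality is a tie.
#'
#' @param pre,post [RatioSet-class] objects (or numbers) with defined
#'   Lac/Bic
#' @return "increase", "decrease" or "tie"
#' @export
classifyResponse <- function(pre, post) {
  val <- function(x) if (is(x, "RatioSet")) x@lacBic else as.numeric(x)
  a <- val(pre); b <- val(post)
  if (is.na(a) || is.na(b))
    stop("unclassifiable: undefined Lac/Bic ratio")
  if (b > a) "increase" else if (b < a) "decrease" else "tie"
}

#' Tumour volume from a stack of per-slice enhancement masks
#'
#' Volume = sum over slices of (enhanced-voxel count x in-plane voxel
#' area) x slice thickness, the standard planimetric estimate from
#' contrast-enhanced imaging.
#'
#' @param maskStack list of logical matrices (one per slice)
#' @param voxelMm length-3 numeric: in-plane dx, dy and slice thickness
#'   (mm)
#' @return list with volume_mm3, n_voxels and voxel_mm
#' @export
tumorVolume <- function(maskStack, voxelMm) {
  if (length(maskStack) == 0) stop("empty-input: no slices")
  d <- dim(maskStack[[1]])
  if (!all(vapply(maskStack, function(m) all(dim(m) == d), logical(1))))
    stop("inconsistent slice dimensions")
  nv <- sum(vapply(maskStack, sum, numeric(1)))
  list(volume_mm3 = nv * prod(voxelMm), n_voxels = nv, voxel_mm = voxelMm)
}

#' Tumour growth rate
#'
#' Ratio of the 48-hour post-treatment tumour volume to the baseline
#' volume.
#'
#' @param volPost,volPre volumes (mm^3); volPre must be > 0
#' @return dimensionless growth factor
#' @export
growthRate <- function(volPost, volPre) {
  if (!is.finite(volPre) || volPre <= 0)
    stop("undefined-growth: baseline volume must be > 0")
  volPost / volPre
}

#' Synthesize a per-slice Gd-enhancement mask stack for a target volume
#'
#' Emulates contrast-enhanced tumour delineation: the tumour is modelled
#' as a sphere of the requested volume, sliced at `sliceMm` spacing;
#' each slice's enhancement disc is rasterized on an `inPlaneMm` grid
#' and thresholded at 50% of the slice maximum of a smooth enhancement
#' profile.
#'
#' @param volumeMm3 target tumour volume (mm^3)
#' @param inPlaneMm in-plane voxel size (mm)
#' @param sliceMm slice thickness (mm)
#' @param gridMm in-plane extent of each mask (mm)
#' @return list of logical matrices, one per slice intersecting the
#'   sphere
#' @export
synthesizeGdMaskStack <- function(volumeMm3, inPlaneMm = 0.25,
                                  sliceMm = 2, gridMm = 40) {
  stopifnot(volumeMm3 > 0)
  r <- (3 * volumeMm3 / (4 * pi))^(1 / 3)
  n <- round(gridMm / inPlaneMm)
  ax <- (seq_len(n) - (n + 1) / 2) * inPlaneMm
  # slice centres covering the sphere
  zc <- seq(-r + sliceMm / 2, r - sliceMm / 2, by = sliceMm)
  if (length(zc) == 0) zc <- 0
  d2 <- outer(ax^2, ax^2, "+")
  lapply(zc, function(z) {
    rs <- sqrt(max(r^2 - z^2, 0))
    # Gaussian enhancement profile whose 50% level falls at the slice
    # radius, so the threshold recovers the sphere cross-section
    sigma2 <- max(rs, inPlaneMm / 2)^2 / (2 * log(2))
    enh <- exp(-d2 / (2 * sigma2))
    enh >= 0.5
  })
}
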