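## Synthetic benchmarks with ground truth.  Every generator is a pure
## function of its parameters and seed (withr::with_seed), so identical
## calls give identical outputs.

#' Generate a planted-regulator network benchmark
#'
#' Emulates the statistical structure of the pipeline's inputs: a PPI
#' background graph, an upstream hub protein connected to a set of planted
#' TFs by high-confidence edges, planted target genes upregulated under
#' load and downregulated under ERK inhibition, decoy TFs with decoy
#' regulons, and background genes carrying pure noise.  Planted cascade
#' scores are drawn high (>= 800) while background scores are uniform in
#' [150, 700], so the cost structure favours — but does not force — the
#' planted cascade.
#'
#' @param nProteins number of background proteins
#' @param nTFs number of TFs (the first \code{nPlantedTFs} are planted)
#' @param nPlantedTFs number of planted (truly active) TFs
#' @param nTargetsPerTF planted targets per planted TF (disjoint sets)
#' @param density background PPI edge probability
#' @param backgroundScores,plantedScores integer score ranges
#' @param plantedLfcMean,plantedLfcSd parameters of the planted
#'   |log2 fold change| (half-normal)
#' @param noiseLfcSd standard deviation of background log2 fold changes
#' @param nBackgroundGenes number of pure-noise genes in the DE tables
#' @param decoyTargetsPerTF decoy regulon size for non-planted TFs
#' @param seed RNG seed
#' @return list with \code{ppi}, \code{tfTargets}, \code{deUp},
#'   \code{deDown} (in the formats the readers produce) and
#'   \code{groundTruth} (planted TFs, hub, target sets, cascade edges).
#' @export
generateNetworkBenchmark <- function(nProteins = 60, nTFs = 8,
                                     nPlantedTFs = 2, nTargetsPerTF = 6,
                                     density = 0.06,
                                     backgroundScores = c(150, 700),
                                     plantedScores = c(800, 999),
                                     plantedLfcMean = 2,
                                     plantedLfcSd = 0.5,
                                     noiseLfcSd = 0.3,
                                     nBackgroundGenes = 40,
                                     decoyTargetsPerTF = 8,
                                     seed = 1) {
  stopifnot(nPlantedTFs <= nTFs, density > 0, density < 1)
  withr::with_seed(as.integer(seed), {
    proteins <- sprintf("P%03d", seq_len(nProteins))
    hub <- "HUB1"
    tfs <- sprintf("TF%02d", seq_len(nTFs))
    planted <- tfs[seq_len(nPlantedTFs)]
    targets <- sprintf("TGT%03d", seq_len(nPlantedTFs * nTargetsPerTF))
    targetSets <- split(targets, rep(planted, each = nTargetsPerTF))
    bg <- sprintf("BG%03d", seq_len(nBackgroundGenes))

    ppiGenes <- c(hub, proteins, tfs)
    pairs <- t(utils::combn(ppiGenes, 2L))
    pick <- stats::runif(nrow(pairs)) < density
    ppi <- data.frame(gene_a = pairs[pick, 1L], gene_b = pairs[pick, 2L],
                      score = round(stats::runif(sum(pick),
                                                 backgroundScores[1L],
                                                 backgroundScores[2L])),
                      stringsAsFactors = FALSE)
    ## guarantee each TF has PPI information
    anchor <- data.frame(gene_a = tfs,
                         gene_b = sample(proteins, nTFs, replace = TRUE),
                         score = round(stats::runif(nTFs,
                                                    backgroundScores[1L],
                                                    backgroundScores[2L])),
                         stringsAsFactors = FALSE)
    ## planted cascade: hub -- planted TFs, high confidence
    cascade <- data.frame(gene_a = hub, gene_b = planted,
                          score = round(stats::runif(nPlantedTFs,
                                                     plantedScores[1L],
                                                     plantedScores[2L])),
                          stringsAsFactors = FALSE)
    ppi <- rbind(ppi, anchor, cascade)
    a <- pmin(ppi$gene_a, ppi$gene_b)
    b <- pmax(ppi$gene_a, ppi$gene_b)
    key <- paste(a, b)
    ppi <- data.frame(gene_a = a, gene_b = b, score = ppi$score,
                      stringsAsFactors = FALSE)
    ppi <- ppi[order(key, -ppi$score), , drop = FALSE]
    ppi <- ppi[!duplicated(paste(ppi$gene_a, ppi$gene_b)), , drop = FALSE]
    ppi <- ppi[order(ppi$gene_a, ppi$gene_b), , drop = FALSE]
    rownames(ppi) <- NULL

    tft <- data.frame(tf = rep(planted, each = nTargetsPerTF),
                      target = targets, stringsAsFactors = FALSE)
    decoys <- setdiff(tfs, planted)
    for (d in decoys) {
      tft <- rbind(tft,
        data.frame(tf = d,
                   target = c(sample(bg, min(decoyTargetsPerTF,
                                             length(bg))),
                              sample(targets, 2L)),
                   stringsAsFactors = FALSE))
    }
    tft <- unique(tft)
    rownames(tft) <- NULL

    allGenes <- c(ppiGenes, targets, bg)
    upLfc <- stats::rnorm(length(allGenes), 0, noiseLfcSd)
    upPadj <- stats::runif(length(allGenes))
    dnLfc <- stats::rnorm(length(allGenes), 0, noiseLfcSd)
    dnPadj <- stats::runif(length(allGenes))
    names(upLfc) <- names(upPadj) <- names(dnLfc) <- names(dnPadj) <- allGenes
    upLfc[targets] <- abs(stats::rnorm(length(targets), plantedLfcMean,
                                       plantedLfcSd))
    upPadj[targets] <- stats::runif(length(targets), 1e-6, 1e-3)
    dnLfc[targets] <- -abs(stats::rnorm(length(targets), plantedLfcMean,
                                        plantedLfcSd))
    dnPadj[targets] <- stats::runif(length(targets), 1e-6, 1e-3)
    upstream <- c(hub, planted)
    upLfc[upstream] <- abs(stats::rnorm(length(upstream), 1.5, 0.3))
    upPadj[upstream] <- stats::runif(length(upstream), 1e-6, 1e-3)

    deUp <- data.frame(gene = allGenes, log2fc = unname(upLfc),
                       padj = unname(upPadj), stringsAsFactors = FALSE)
    deDown <- data.frame(gene = allGenes, log2fc = unname(dnLfc),
                         padj = unname(dnPadj), stringsAsFactors = FALSE)

    cascadeEdges <- rbind(
      data.frame(u = pmin(hub, planted), v = pmax(hub, planted),
                 stringsAsFactors = FALSE),
      data.frame(u = tft$tf[tft$tf %in% planted],
                 v = paste0(tft$target[tft$tf %in% planted], ":rna"),
                 stringsAsFactors = FALSE))

    list(ppi = ppi, tfTargets = tft, deUp = deUp, deDown = deDown,
         groundTruth = list(hub = hub, plantedTFs = planted,
                            decoyTFs = decoys, targetSets = targetSets,
                            plantedTargets = targets,
                            cascadeEdges = cascadeEdges,
                            nTargetsPerTF = nTargetsPerTF))
  })
}

## pixel coordinate grids
.grid <- function(size) {
  list(x = matrix(rep(seq_len(size), each = size), size),
       y = matrix(rep(seq_len(size), times = size), size))
}

#' Generate a synthetic DAPI nucleus image with ground truth
#'
#' Elliptical nuclei on a dark background, optional smooth intra-nuclear
#' texture, bright Gaussian heterochromatin foci whose centres fall in the
#' peripheral shell with probability \code{peripheralBias}, optional
#' Gaussian blur and additive noise.  Intensities are on a 16-bit scale.
#'
#' @param size image side in pixels
#' @param nNuclei number of nuclei (placed on a jittered grid, disjoint)
#' @param centers optional n x 2 matrix of nucleus centres (overrides the
#'   grid; allows deliberately overlapping nuclei)
#' @param radiusRange semi-major axis range in pixels
#' @param fociPerNucleus planted heterochromatin foci per nucleus
#' @param focusRadiusRange focus radius range in pixels
#' @param contrast peak focus intensity as a multiple of the nuclear base
#'   intensity
#' @param peripheralBias probability that a focus centre lies in the
#'   peripheral shell (within \code{shellWidthGT} of the boundary)
#' @param shellWidthGT generator shell width in pixels
#' @param baseIntensity,backgroundIntensity nuclear / background levels
#' @param textureSd sd of the smooth intra-nuclear texture (0 disables)
#' @param noiseSd additive Gaussian noise sd (0 disables)
#' @param blurSigma final Gaussian blur sigma (0 disables)
#' @param minFocusSeparation minimum distance between focus centres
#' @param seed RNG seed
#' @return list with \code{image}, \code{nucleusMask} (labels),
#'   \code{focusMask} (labels), \code{focusPeripheral} (logical per
#'   focus), \code{focusArea} (pixels per focus) and \code{params}.
#' @export
generateNucleusImage <- function(size = 256, nNuclei = 5, centers = NULL,
                                 radiusRange = c(18, 26),
                                 fociPerNucleus = 4,
                                 focusRadiusRange = c(2.5, 4),
                                 contrast = 3, peripheralBias = 0.5,
                                 shellWidthGT = 5,
                                 baseIntensity = 8000,
                                 backgroundIntensity = 500,
                                 textureSd = 300, noiseSd = 200,
                                 blurSigma = 1,
                                 minFocusSeparation = 10, seed = 1) {
  stopifnot(peripheralBias >= 0, peripheralBias <= 1)
  withr::with_seed(as.integer(seed), {
    g <- .grid(size)
    if (is.null(centers)) {
      k <- ceiling(sqrt(nNuclei))
      step <- size / k
      cx <- (rep(seq_len(k), each = k) - 0.5) * step
      cy <- (rep(seq_len(k), times = k) - 0.5) * step
      ord <- seq_len(nNuclei)
      centers <- cbind(cx[ord], cy[ord]) +
        matrix(stats::runif(2 * nNuclei, -5, 5), ncol = 2L)
    }
    nNuclei <- nrow(centers)
    img <- matrix(backgroundIntensity, size, size)
    nucleusMask <- matrix(0L, size, size)
    focusMask <- matrix(0L, size, size)
    focusPeripheral <- logical(0)
    focusArea <- integer(0)
    focusId <- 0L
    for (i in seq_len(nNuclei)) {
      a <- stats::runif(1, radiusRange[1L], radiusRange[2L])
      b <- a * stats::runif(1, 0.75, 1)
      th <- stats::runif(1, 0, pi)
      dx <- g$x - centers[i, 1L]
      dy <- g$y - centers[i, 2L]
      xr <- dx * cos(th) + dy * sin(th)
      yr <- -dx * sin(th) + dy * cos(th)
      rho <- sqrt((xr / a)^2 + (yr / b)^2)
      inside <- rho <= 1
      nucleusMask[inside] <- i
      img[inside] <- baseIntensity
      if (textureSd > 0) {
        tex <- matrix(stats::rnorm(size * size), size, size)
        tex <- as.matrix(EBImage::gblur(EBImage::Image(tex), sigma = 6))
        tex <- tex / stats::sd(tex) * textureSd
        img[inside] <- img[inside] + tex[inside]
      }
      ## plant foci; boundary distance approximated by (1 - rho) * b
      if (fociPerNucleus > 0) {
        bdist <- (1 - rho) * b
        placed <- matrix(numeric(0), ncol = 2L)
        for (f in seq_len(fociPerNucleus)) {
          wantShell <- stats::runif(1) < peripheralBias
          for (try in seq_len(400L)) {
            cand <- which(inside & if (wantShell) bdist <= shellWidthGT
                          else bdist > shellWidthGT)
            if (!length(cand)) cand <- which(inside)
            px <- cand[sample.int(length(cand), 1L)]
            fx <- g$x[px]; fy <- g$y[px]
            if (!nrow(placed) ||
                min(sqrt((placed[, 1L] - fx)^2 + (placed[, 2L] - fy)^2)) >=
                minFocusSeparation) break
          }
          placed <- rbind(placed, c(fx, fy))
          fr <- stats::runif(1, focusRadiusRange[1L], focusRadiusRange[2L])
          d2 <- (g$x - fx)^2 + (g$y - fy)^2
          ## foci are uniform discs softened only by the image-level blur,
          ## so their thresholded footprint matches the planted area
          fsel <- inside & d2 <= fr^2
          img[fsel] <- img[fsel] + (contrast - 1) * baseIntensity
          focusId <- focusId + 1L
          focusMask[fsel] <- focusId
          focusPeripheral <- c(focusPeripheral, bdist[px] <= shellWidthGT)
          focusArea <- c(focusArea, sum(fsel))
        }
      }
    }
    if (blurSigma > 0)
      img <- as.matrix(EBImage::gblur(EBImage::Image(img / 65535),
                                      sigma = blurSigma)) * 65535
    if (noiseSd > 0)
      img <- img + matrix(stats::rnorm(size * size, 0, noiseSd), size, size)
    img <- pmin(pmax(img, 0), 65535)
    list(image = img, nucleusMask = nucleusMask, focusMask = focusMask,
         focusPeripheral = focusPeripheral, focusArea = focusArea,
         params = list(size = size, nNuclei = nNuclei,
                       peripheralBias = peripheralBias,
                       fociPerNucleus = fociPerNucleus,
                       shellWidthGT = shellWidthGT, seed = seed))
  })
}

#' Generate a synthetic spheroid-spreading image with ground truth
#'
#' A dense bright core disc plus individual cells scattered out to the
#' migration radius.  Unless \code{nCells} is given, the cell count scales
#' with the annulus area (constant migrating-cell density), emulating
#' progressive outward migration.  Returns matched DAPI-like and
#' actin-like channels with identical geometry.
#'
#' @param size image side in pixels
#' @param coreRadius initial spheroid radius (pixels)
#' @param migrationRadius maximal migration radius (>= coreRadius)
#' @param nCells number of migrating cells (default: density-scaled)
#' @param cellDensity cells per pixel^2 of annulus when \code{nCells} is
#'   NULL
#' @param cellRadiusRange cell radius range (pixels)
#' @param coreIntensity,cellIntensity,backgroundIntensity 16-bit levels
#' @param noiseSd additive noise sd (0 disables)
#' @param blurSigma Gaussian blur sigma (0 disables)
#' @param seed RNG seed
#' @return list with \code{dapi}, \code{actin}, \code{spreadMask},
#'   \code{coreMask}, \code{spreadArea}, \code{coreArea},
#'   \code{outsideCellArea} and \code{params}.
#' @export
generateSpheroidImage <- function(size = 512, coreRadius = 60,
                                  migrationRadius = 120, nCells = NULL,
                                  cellDensity = 0.006,
                                  cellRadiusRange = c(3, 5),
                                  coreIntensity = 9000,
                                  cellIntensity = 7000,
                                  backgroundIntensity = 300,
                                  noiseSd = 200, blurSigma = 1, seed = 1) {
  stopifnot(migrationRadius >= coreRadius)
  withr::with_seed(as.integer(seed), {
    if (is.null(nCells))
      nCells <- round(cellDensity *
                      pi * (migrationRadius^2 - coreRadius^2))
    g <- .grid(size)
    c0 <- size / 2
    d <- sqrt((g$x - c0)^2 + (g$y - c0)^2)
    coreMask <- d <= coreRadius
    spreadMask <- coreMask
    cellMaskOutside <- matrix(FALSE, size, size)
    img <- matrix(backgroundIntensity, size, size)
    img[coreMask] <- coreIntensity
    if (nCells > 0) for (i in seq_len(nCells)) {
      cr <- stats::runif(1, cellRadiusRange[1L], cellRadiusRange[2L])
      lo <- max(0, coreRadius - cr - 1)
      hi <- max(lo, migrationRadius - cr - 1)
      rr <- stats::runif(1, lo, hi)
      ang <- stats::runif(1, 0, 2 * pi)
      fx <- c0 + rr * cos(ang)
      fy <- c0 + rr * sin(ang)
      cm <- (g$x - fx)^2 + (g$y - fy)^2 <= cr^2
      img[cm & !coreMask] <- cellIntensity
      spreadMask <- spreadMask | cm
      cellMaskOutside <- cellMaskOutside | (cm & !coreMask)
    }
    actin <- img
    if (blurSigma > 0) {
      img <- as.matrix(EBImage::gblur(EBImage::Image(img / 65535),
                                      sigma = blurSigma)) * 65535
      actin <- as.matrix(EBImage::gblur(EBImage::Image(actin / 65535),
                                        sigma = blurSigma)) * 65535
    }
    if (noiseSd > 0) {
      img <- img + matrix(stats::rnorm(size * size, 0, noiseSd), size, size)
      actin <- actin +
        matrix(stats::rnorm(size * size, 0, noiseSd), size, size)
    }
    img <- pmin(pmax(img, 0), 65535)
    actin <- pmin(pmax(actin, 0), 65535)
    list(dapi = img, actin = actin, spreadMask = spreadMask,
         coreMask = coreMask, spreadArea = sum(spreadMask),
         coreArea = sum(coreMask),
         outsideCellArea = sum(cellMaskOutside),
         params = list(size = size, coreRadius = coreRadius,
                       migrationRadius = migrationRadius, nCells = nCells,
                       seed = seed))
  })
}
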