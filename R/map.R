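#' Build a genetic map for introgression-line simulation
#'
#' Constructs the marker grid and target-segment tiling used by all
#' simulations. The default reproduces a maize-style genome of 10 equally
#' sized chromosomes of 200 cM, markers equally spaced at 1 cM, and 20 cM
#' target segments tiling each chromosome without gap or overlap (100
#' segments, 10 per chromosome).
#'
#' Markers are placed at segment-interior positions `spacing/2,
#' 3*spacing/2, ...` so every target segment contains exactly
#' `segment_length / marker_spacing` markers and no marker sits on a segment
#' or chromosome-half boundary. Segment intervals are half-open
#' `[start, end)` in cM.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in cM (all chromosomes equal).
#' @param marker_spacing Distance between adjacent markers in cM.
#' @param segment_length Target-segment length in cM; must divide
#'   `chrom_length` and be a multiple of `marker_spacing`.
#' @return An object of class `il_map`: a list with the map geometry and
#'   per-marker chromosome / position / segment / half assignments.
#' @examples
#' m <- il_map()
#' m$n_markers      # 2000
#' m$n_segments     # 100
#' @export
il_map <- function(n_chromosomes = 10, chrom_length = 200,
                   marker_spacing = 1, segment_length = 20) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0, marker_spacing > 0,
            segment_length > 0)
  if (abs(chrom_length / segment_length -
          round(chrom_length / segment_length)) > 1e-9)
    stop("chromosome length (", chrom_length,
         " cM) is not divisible by segment length (", segment_length, " cM)")
  if (abs(segment_length / marker_spacing -
          round(segment_length / marker_spacing)) > 1e-9)
    stop("segment length (", segment_length,
         " cM) is not divisible by marker spacing (", marker_spacing, " cM)")
  mpc <- as.integer(round(chrom_length / marker_spacing))
  pos_within <- marker_spacing / 2 + (seq_len(mpc) - 1) * marker_spacing
  segs_per_chrom <- as.integer(round(chrom_length / segment_length))
  chrom <- rep(seq_len(n_chromosomes), each = mpc)
  pos <- rep(pos_within, times = n_chromosomes)
  seg_within <- findInterval(pos_within, seq(0, chrom_length, by = segment_length),
                             rightmost.closed = FALSE)
  segment <- rep(seg_within, times = n_chromosomes) +
    (chrom - 1L) * segs_per_chrom
  half_within <- ifelse(pos_within < chrom_length / 2, 1L, 2L)
  half <- rep(half_within, times = n_chromosomes) + (chrom - 1L) * 2L
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length,
    marker_spacing = marker_spacing,
    segment_length = segment_length,
    markers_per_chrom = mpc,
    n_markers = as.integer(n_chromosomes * mpc),
    segments_per_chrom = segs_per_chrom,
    n_segments = as.integer(n_chromosomes * segs_per_chrom),
    pos_within = pos_within,
    chrom = as.integer(chrom),
    pos = pos,
    segment = as.integer(segment),
    half = as.integer(half),
    total_length = n_chromosomes * chrom_length
  ), class = "il_map")
}

#' @export
print.il_map <- function(x, ...) {
  cat("<il_map> ", x$n_chromosomes, " chromosomes x ", x$chrom_length,
      " cM, ", x$n_markers, " markers (", x$marker_spacing, " cM spacing), ",
      x$n_segments, " target segments of ", x$segment_length, " cM\n",
      sep = "")
  invisible(x)
}

#' Marker table of a genetic map
#'
#' @param map An [il_map()].
#' @return A tibble with one row per marker: `marker`, `chrom`, `pos` (cM),
#'   `segment` (target-segment index) and `half` (chromosome-half index).
#' @export
marker_table <- function(map) {
  stopifnot(inherits(map, "il_map"))
  tibble::tibble(marker = seq_len(map$n_markers), chrom = map$chrom,
                 pos = map$pos, segment = map$segment, half = map$half)
}

#' Partition the genome into selection regions
#'
#' Selection in the backcross generations operates on one of three region
#' systems: 10 complete chromosomes, 20 chromosome halves, or 100 target
#' segments (default map). Regions are contiguous marker blocks; halves
#' split each chromosome at `chrom_length / 2`.
#'
#' @param map An [il_map()].
#' @param kind One of `"chromosome"`, `"half"`, `"segment"`.
#' @return A tibble with one row per region: `region`, `kind`, `chrom`,
#'   `start`, `end` (half-open cM interval), `col_start`, `col_end` (marker
#'   column range) and `n_markers`.
#' @examples
#' nrow(region_partition(il_map(), "half"))   # 20
#' @export
region_partition <- function(map, kind = c("chromosome", "half", "segment")) {
  stopifnot(inherits(map, "il_map"))
  kind <- match.arg(kind)
  idx <- switch(kind, chromosome = map$chrom, half = map$half,
                segment = map$segment)
  n_regions <- max(idx)
  first <- match(seq_len(n_regions), idx)
  last <- map$n_markers + 1L - match(seq_len(n_regions), rev(idx))
  tibble::tibble(
    region = seq_len(n_regions),
    kind = kind,
    chrom = map$chrom[first],
    start = map$pos[first] - map$marker_spacing / 2,
    end = map$pos[last] + map$marker_spacing / 2,
    col_start = first,
    col_end = last,
    n_markers = last - first + 1L
  )
}
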