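# Intact (full-length) provirus assembly and flank geometry.

#' Default full-length element criteria per ERV superfamily
#'
#' A full-length element is an LTR-internal-LTR run where both LTRs carry the
#' identical family annotation, internal segments belong to the superfamily's
#' internal family, adjacent components are separated by at most
#' `gap_tolerance` bp, and the total span falls inside `[min_span, max_span]`.
#' The span windows are configuration, not biology measured here: MERVL
#' full-length elements are ~6 kb, IAPEz ~7 kb, MMERVK10C ~6-9 kb.
#'
#' @return data.frame with columns `superfamily`, `ltr_family`,
#'   `internal_family`, `min_span`, `max_span`, `gap_tolerance`
#' @export
default_family_spec <- function() {
  data.frame(
    superfamily = c("MERVL", "IAPEz", "MMERVK10C"),
    ltr_family = c("MT2_Mm", "IAPLTR1_Mm", "RLTR10C"),
    internal_family = c("MERVL-int", "IAPEz-int", "MMERVK10C-int"),
    min_span = c(5000L, 6000L, 5000L),
    max_span = c(8000L, 9000L, 10000L),
    gap_tolerance = c(100L, 100L, 100L),
    stringsAsFactors = FALSE
  )
}

#' Assemble full-length LTR-internal-LTR elements
#'
#' Scans repeat segments for maximal runs of the form
#' LTR, internal+, LTR on one chromosome and strand, where both LTRs have the
#' identical family string, internal segments match the superfamily's
#' internal family, component gaps are within tolerance, and the total span
#' is inside the superfamily's length window. Components consumed by one
#' element are not reused. Non-qualifying runs are skipped; per-family skip
#' counts are returned as an attribute.
#'
#' @param elements repeat element data.frame (as from
#'   [read_repeat_annotation()])
#' @param family_spec criteria table, see [default_family_spec()]
#' @return data.frame of full-length elements: `element_id`, `superfamily`,
#'   `chrom`, `start`, `end`, `strand`, `ltr5_id`, `ltr3_id`, `n_internal`;
#'   attribute `skipped` holds per-superfamily skip counts
#' @export
assemble_full_length_elements <- function(elements,
                                          family_spec = default_family_spec()) {
  out <- list()
  skipped <- stats::setNames(integer(nrow(family_spec)),
                             family_spec$superfamily)
  if (nrow(elements)) {
    elements <- elements[order(elements$chrom, elements$start), ]
    for (fi in seq_len(nrow(family_spec))) {
      fs <- family_spec[fi, ]
      cand <- elements[elements$family %in%
                         c(fs$ltr_family, fs$internal_family), ]
      if (!nrow(cand)) next
      for (key in unique(paste(cand$chrom, cand$strand))) {
        grp <- cand[paste(cand$chrom, cand$strand) == key, ]
        grp <- grp[order(grp$start), ]
        used <- logical(nrow(grp))
        i <- 1L
        while (i <= nrow(grp)) {
          if (used[i] || grp$family[i] != fs$ltr_family) { i <- i + 1L; next }
          # extend through contiguous internal segments to a closing LTR
          j <- i + 1L
          n_int <- 0L
          ok <- FALSE
          prev_end <- grp$end[i]
          while (j <= nrow(grp) && !used[j] &&
                 grp$start[j] - prev_end <= fs$gap_tolerance) {
            if (grp$family[j] == fs$internal_family) {
              n_int <- n_int + 1L
              prev_end <- grp$end[j]
              j <- j + 1L
            } else if (grp$family[j] == fs$ltr_family) {
              ok <- n_int > 0L
              break
            } else break
          }
          if (ok) {
            span <- grp$end[j] - grp$start[i]
            if (span >= fs$min_span && span <= fs$max_span) {
              used[i:j] <- TRUE
              out[[length(out) + 1L]] <- data.frame(
                element_id = sprintf("%s_FL_%s_%d", fs$superfamily,
                                     grp$chrom[i], grp$start[i]),
                superfamily = fs$superfamily,
                chrom = grp$chrom[i], start = grp$start[i],
                end = grp$end[j], strand = grp$strand[i],
                ltr5_id = if (grp$strand[i] == "+") grp$element_id[i]
                          else grp$element_id[j],
                ltr3_id = if (grp$strand[i] == "+") grp$element_id[j]
                          else grp$element_id[i],
                n_internal = n_int,
                stringsAsFactors = FALSE
              )
              i <- j + 1L
              next
            }
            skipped[fs$superfamily] <- skipped[fs$superfamily] + 1L
          }
          i <- i + 1L
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    element_id = character(), superfamily = character(),
    chrom = character(), start = integer(), end = integer(),
    strand = character(), ltr5_id = character(), ltr3_id = character(),
    n_internal = integer(), stringsAsFactors = FALSE
  )
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Flank bin geometry for a set of elements
#'
#' Tiles the `span` bp flanking each element on both sides into `bin_width`
#' bp bins, oriented by element strand: bin 0 is always adjacent to the
#' element boundary and the 5' side of a minus-strand element lies at higher
#' genomic coordinates. Bins running past the chromosome are truncated and
#' flagged.
#'
#' @param elements full-length element data.frame
#'   (from [assemble_full_length_elements()]); any table with `element_id`,
#'   `chrom`, `start`, `end`, `strand` works
#' @param span flank width in bp (default 6000)
#' @param bin_width bin width in bp (default 50)
#' @param chrom_lengths named integer vector of chromosome lengths, used for
#'   truncation at the right edge (optional)
#' @return data.frame: `element_id`, `side` ("5prime"/"3prime"),
#'   `bin_index` (0-based, 0 at the boundary), `chrom`, `start`, `end`,
#'   `truncated`
#' @export
flank_bins <- function(elements, span = 6000L, bin_width = 50L,
                       chrom_lengths = NULL) {
  if (span <= 0 || bin_width <= 0) {
    stop("span and bin_width must be positive", call. = FALSE)
  }
  if (span %% bin_width != 0) {
    stop("span must be divisible by bin_width", call. = FALSE)
  }
  n_bins <- span %/% bin_width
  k <- seq_len(n_bins) - 1L
  res <- lapply(seq_len(nrow(elements)), function(i) {
    el <- elements[i, ]
    # genomic bins left of start (walking outward) and right of end
    left <- data.frame(start = el$start - (k + 1L) * bin_width,
                       end = el$start - k * bin_width)
    right <- data.frame(start = el$end + k * bin_width,
                        end = el$end + (k + 1L) * bin_width)
    if (el$strand == "-") {
      five <- right; three <- left
    } else {
      five <- left; three <- right
    }
    df <- rbind(
      data.frame(element_id = el$element_id, side = "5prime", bin_index = k,
                 chrom = el$chrom, five, stringsAsFactors = FALSE),
      data.frame(element_id = el$element_id, side = "3prime", bin_index = k,
                 chrom = el$chrom, three, stringsAsFactors = FALSE)
    )
    df
  })
  bins <- do.call(rbind, res)
  bins$truncated <- FALSE
  clip <- bins$start < 0L
  bins$truncated[clip & bins$end > 0L] <- TRUE
  bins$start[clip] <- pmax(bins$start[clip], 0L)
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[bins$chrom]
    over <- !is.na(len) & bins$end > len
    bins$truncated[over & bins$start < len[over]] <- TRUE
    bins$end[over] <- pmin(bins$end[over], len[over])
  }
  # fully out-of-range bins collapse to empty intervals at the edge
  bins$end <- pmax(bins$end, bins$start)
  rownames(bins) <- NULL
  bins
}

#' Distance from a gene TSS to the nearest LTR of listed families
#'
#' Returns 0 when the TSS falls inside an element of a listed family,
#' otherwise the minimum gap in bp to the nearest listed element on the same
#' chromosome, or `NA` if that chromosome carries none. Ties break toward
#' the element at the lower genomic coordinate (which does not affect the
#' distance value).
#'
#' @param genes gene table with `gene_id`, `chrom`, `tss`
#' @param elements repeat element data.frame
#' @param ltr_families family names to consider (default MT2/MT2A/MT2C)
#' @return named numeric vector of distances, `NA` where no listed element
#'   exists on the gene's chromosome
#' @export
nearest_ltr_distance <- function(genes, elements,
                                 ltr_families = c("MT2_Mm", "MT2A", "MT2C")) {
  check_cols(genes, c("gene_id", "chrom", "tss"))
  targets <- elements[elements$family %in% ltr_families, , drop = FALSE]
  out <- stats::setNames(rep(NA_real_, nrow(genes)), genes$gene_id)
  if (!nrow(targets)) return(out)
  for (ch in unique(genes$chrom)) {
    tt <- targets[targets$chrom == ch, ]
    gi <- which(genes$chrom == ch)
    if (!nrow(tt)) next
    for (g in gi) {
      tss <- genes$tss[g]
      inside <- tss >= tt$start & tss < tt$end
      if (any(inside)) {
        out[g] <- 0
      } else {
        gap <- pmax(tt$start - tss, tss - tt$end, 0)
        out[g] <- min(gap)
      }
    }
  }
  out
}
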