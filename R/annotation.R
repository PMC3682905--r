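# Repeat and gene annotation I/O.
#
# Repeat elements are plain data.frames (one row per annotated segment):
#   element_id, family, erv_class, part ("LTR"/"internal"), chrom, start, end,
#   strand -- coordinates 0-based half-open.
# Gene models are a list of two data.frames: `genes` (gene_id, name, chrom,
# strand, tss, transcript_length, in_refseq, in_ensembl) and `exons`
# (gene_id, exon_index, chrom, start, end, strand), exon_index counted in
# transcript orientation (1 = first exon).

#' Default repeat-part lookup table
#'
#' Maps repeat family names to their role in a provirus: LTR or internal
#' segment. Families ending in "-int" are internal; the LTR families of the
#' MERVL, IAPEz and MMERVK10C ERV groups are listed explicitly. Extend or
#' replace this table to cover additional annotation sets.
#'
#' @return data.frame with columns `family`, `part`, `erv_class`
#' @export
default_part_table <- function() {
  data.frame(
    family = c("MT2_Mm", "MT2A", "MT2B", "MT2C", "MERVL-int", "ORR1A3-int",
               "IAPLTR1_Mm", "IAPLTR1a_Mm", "IAPEz-int",
               "RLTR10C", "MMERVK10C-int"),
    part = c("LTR", "LTR", "LTR", "LTR", "internal", "internal",
             "LTR", "LTR", "internal",
             "LTR", "internal"),
    erv_class = c("III", "III", "III", "III", "III", "III",
                  "II", "II", "II",
                  "II", "II"),
    stringsAsFactors = FALSE
  )
}

infer_part <- function(family, part_table, strict = FALSE) {
  idx <- match(family, part_table$family)
  part <- part_table$part[idx]
  unknown <- is.na(idx)
  if (any(unknown)) {
    # fall back on the "-int" naming convention before giving up
    looks_internal <- grepl("-int$", family[unknown], ignore.case = TRUE)
    if (strict) {
      stop("unknown repeat families: ",
           paste(unique(family[unknown]), collapse = ", "), call. = FALSE)
    }
    warning("unknown repeat families treated as internal: ",
            paste(unique(family[unknown & !looks_internal]), collapse = ", "))
    part[unknown] <- "internal"
  }
  part
}

infer_class <- function(family, part_table) {
  cls <- part_table$erv_class[match(family, part_table$family)]
  cls[is.na(cls)] <- "other"
  cls
}

#' Read a repeat annotation file
#'
#' Supports BED6 (0-based half-open, family name in column 4) and
#' RepeatMasker `.out` (1-based inclusive `begin`/`end`, converted on read).
#' The segment role (LTR vs internal) is inferred from the family name via
#' `part_table`.
#'
#' @param path annotation file
#' @param dialect `"bed6"` or `"rmout"`
#' @param part_table family-to-part lookup, see [default_part_table()]
#' @param strict error (rather than warn) on families absent from
#'   `part_table`
#' @return data.frame of repeat elements (see package overview for columns)
#' @export
read_repeat_annotation <- function(path, dialect = c("bed6", "rmout"),
                                   part_table = default_part_table(),
                                   strict = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(empty_repeats())
  }
  if (dialect == "bed6") {
    fields <- strsplit(lines, "\t|[ ]+")
    bad <- which(vapply(fields, length, 1L) < 6L)
    if (length(bad)) {
      stop(sprintf("malformed BED6 line %d in %s", bad[1], path),
           call. = FALSE)
    }
    m <- do.call(rbind, lapply(fields, `[`, 1:6))
    start <- suppressWarnings(as.integer(m[, 2]))
    end <- suppressWarnings(as.integer(m[, 3]))
    if (anyNA(start) || anyNA(end)) {
      stop(sprintf("malformed BED6 line %d in %s: non-numeric coordinate",
                   which(is.na(start) | is.na(end))[1], path), call. = FALSE)
    }
    df <- data.frame(family = m[, 4], chrom = m[, 1], start = start,
                     end = end, strand = m[, 6], stringsAsFactors = FALSE)
  } else {
    # RepeatMasker .out: 3 header lines, whitespace-separated columns;
    # col 5 = query, 6 = begin (1-based), 7 = end (inclusive), 9 = strand
    # (+ or C), 10 = repeat family name.
    body <- grep("^\\s*[0-9]", lines, value = TRUE)
    fields <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(fields, length, 1L) < 10L)
    if (length(bad)) {
      stop(sprintf("malformed RepeatMasker line %d in %s", bad[1], path),
           call. = FALSE)
    }
    m <- do.call(rbind, lapply(fields, `[`, 1:10))
    begin <- suppressWarnings(as.integer(m[, 6]))
    endi <- suppressWarnings(as.integer(m[, 7]))
    if (anyNA(begin) || anyNA(endi)) {
      stop("malformed RepeatMasker record: non-numeric coordinate",
           call. = FALSE)
    }
    df <- data.frame(
      family = m[, 10], chrom = m[, 5],
      start = begin - 1L, end = endi,
      strand = ifelse(m[, 9] == "C", "-", "+"),
      stringsAsFactors = FALSE
    )
  }
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop(sprintf("invalid interval on line %d: start %d end %d",
                 bad[1], df$start[bad[1]], df$end[bad[1]]), call. = FALSE)
  }
  data.frame(
    element_id = sprintf("%s_%d", df$family, seq_len(nrow(df))),
    family = df$family,
    erv_class = infer_class(df$family, part_table),
    part = infer_part(df$family, part_table, strict = strict),
    chrom = df$chrom, start = df$start, end = df$end, strand = df$strand,
    stringsAsFactors = FALSE
  )
}

empty_repeats <- function() {
  data.frame(element_id = character(), family = character(),
             erv_class = character(), part = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Write repeat elements as BED6
#'
#' Family name goes in the BED name field; score is 0. Round-trips through
#' [read_repeat_annotation()] up to element_id regeneration.
#' @param repeats repeat element data.frame
#' @param path output file
#' @export
write_repeats_bed <- function(repeats, path) {
  check_cols(repeats, c("chrom", "start", "end", "family", "strand"))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", repeats$chrom,
                   repeats$start, repeats$end, repeats$family,
                   repeats$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write gene models as GTF
#'
#' Emits one `exon` feature per exon with gene-level attributes
#' (`gene_id`, `gene_name`, `transcript_length`, `in_refseq`,
#' `in_ensembl`). Coordinates are converted to GTF's 1-based inclusive
#' convention on write.
#' @param gene_models list with `genes` and `exons` data.frames
#' @param path output file
#' @export
write_gene_models_gtf <- function(gene_models, path) {
  genes <- gene_models$genes
  exons <- gene_models$exons
  i <- match(exons$gene_id, genes$gene_id)
  attrs <- sprintf(
    paste0('gene_id "%s"; gene_name "%s"; transcript_length %d; ',
           'in_refseq "%s"; in_ensembl "%s"; exon_number %d;'),
    exons$gene_id, genes$name[i], genes$transcript_length[i],
    ifelse(genes$in_refseq[i], "TRUE", "FALSE"),
    ifelse(genes$in_ensembl[i], "TRUE", "FALSE"),
    exons$exon_index
  )
  lines <- sprintf("%s\tervpipe\texon\t%d\t%d\t.\t%s\t.\t%s",
                   exons$chrom, exons$start + 1L, exons$end,
                   exons$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Reads exon features via rtracklayer and reconstructs the `genes` +
#' `exons` pair of tables used throughout the package. The TSS is the
#' strand-aware 5' end of the first exon.
#' @param path GTF file (as written by [write_gene_models_gtf()] or any GTF
#'   with `gene_id` attributes on exon features)
#' @return list with `genes` and `exons` data.frames
#' @export
read_gene_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  ex <- as_table0(gr)
  ex$gene_id <- gr$gene_id
  ex$exon_index <- if (!is.null(gr$exon_number)) {
    as.integer(gr$exon_number)
  } else {
    stats::ave(ex$start, ex$gene_id, FUN = seq_along)
  }
  exons <- ex[order(ex$gene_id, ex$exon_index),
              c("gene_id", "exon_index", "chrom", "start", "end", "strand")]
  rownames(exons) <- NULL
  first <- exons[exons$exon_index == 1L, ]
  per_gene <- split(exons, exons$gene_id)[first$gene_id]
  genes <- data.frame(
    gene_id = first$gene_id,
    name = if (!is.null(gr$gene_name)) {
      gr$gene_name[match(first$gene_id, gr$gene_id)]
    } else first$gene_id,
    chrom = first$chrom,
    strand = first$strand,
    tss = ifelse(first$strand == "+", first$start, first$end - 1L),
    transcript_length = vapply(per_gene,
                               function(e) sum(e$end - e$start), 0L),
    in_refseq = if (!is.null(gr$in_refseq)) {
      gr$in_refseq[match(first$gene_id, gr$gene_id)] == "TRUE"
    } else TRUE,
    in_ensembl = if (!is.null(gr$in_ensembl)) {
      gr$in_ensembl[match(first$gene_id, gr$gene_id)] == "TRUE"
    } else TRUE,
    stringsAsFactors = FALSE
  )
  rownames(genes) <- NULL
  list(genes = genes, exons = exons)
}
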