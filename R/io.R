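COUNT_COLS <- c("chrom", "pos", "ref", "alt",
                "g_ref", "g_alt", "y_ref", "y_alt")

#' Read a per-site allele count table
#'
#' Reads biallelic per-site read depths for the two bulks either from the
#' canonical tab-separated count table (header: chrom, pos, ref, alt, g_ref,
#' g_alt, y_ref, y_alt; 1-based positions) or from a VCFv4.2 file with two
#' samples carrying the AD FORMAT field. VCF records that are not biallelic
#' SNPs are skipped and counted; the skip count is attached as attribute
#' `n_skipped` and reported via `message()`. Output is sorted by (chrom,
#' pos); duplicate positions are an error.
#'
#' @param path Input file.
#' @param format `"tsv"`, `"vcf"`, or `"auto"` (by file extension).
#' @param sample_g,sample_y VCF sample names holding the green (wild
#'   phenotype) and yellow (mutant phenotype) bulk.
#' @return Count table data.frame.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "vcf"),
                        sample_g = "G", sample_y = "Y") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  counts <- if (format == "tsv") {
    df <- read.delim(path, colClasses = c(chrom = "character"))
    if (!all(COUNT_COLS %in% names(df)))
      stop("count table must have columns: ", paste(COUNT_COLS, collapse = ", "))
    df <- df[COUNT_COLS]
    attr(df, "n_skipped") <- 0L
    df
  } else {
    read_counts_vcf(path, sample_g, sample_y)
  }
  if (any(counts$pos < 1)) stop("positions must be >= 1 (1-based)")
  if (any(unlist(counts[c("g_ref", "g_alt", "y_ref", "y_alt")]) < 0))
    stop("read counts must be non-negative")
  if (any(counts$ref == counts$alt)) stop("ref and alt alleles must differ")
  n_skipped <- attr(counts, "n_skipped")
  ord <- order(counts$chrom, counts$pos)
  counts <- counts[ord, , drop = FALSE]
  if (any(duplicated(counts[c("chrom", "pos")])))
    stop("duplicate positions in count input")
  rownames(counts) <- NULL
  attr(counts, "n_skipped") <- n_skipped
  counts
}

read_counts_vcf <- function(path, sample_g, sample_y) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos <- as.numeric(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  if (!identical(order(match(chrom, unique(chrom)), pos), seq_along(pos)))
    stop("VCF records must be sorted by (CHROM, POS)")
  snp <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0)
    message(n_skipped, " non-biallelic-SNP record(s) skipped")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || !all(c(sample_g, sample_y) %in% colnames(ad)))
    stop("VCF must carry the AD FORMAT field for samples '", sample_g,
         "' and '", sample_y, "'")
  parse_ad <- function(x, rec) {
    if (is.na(x)) stop("missing AD at record ", rec)
    as.numeric(strsplit(x, ",", fixed = TRUE)[[1]][1:2])
  }
  keep <- which(snp)
  recs <- paste0(chrom[keep], ":", pos[keep])
  g <- t(vapply(seq_along(keep), function(i)
    parse_ad(ad[keep[i], sample_g], recs[i]), numeric(2)))
  y <- t(vapply(seq_along(keep), function(i)
    parse_ad(ad[keep[i], sample_y], recs[i]), numeric(2)))
  out <- data.frame(chrom = chrom[keep], pos = pos[keep],
                    ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                    g_ref = g[, 1], g_alt = g[, 2],
                    y_ref = y[, 1], y_alt = y[, 2])
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write the canonical count table
#'
#' @param counts Count table data.frame.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  write.table(counts[COUNT_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write counts as a minimal two-sample VCF
#'
#' Emits a plain-text VCFv4.2 file with samples `G` and `Y` and the AD
#' FORMAT field, for interoperability with variant-centric tools.
#'
#' @param counts Count table data.frame.
#' @param path Output path.
#' @param sample_g,sample_y Sample names to write.
#' @export
write_vcf_counts <- function(counts, path, sample_g = "G", sample_y = "Y") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=bsamapr-", as.character(packageVersion("bsamapr"))),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_g, sample_y, sep = "\t")), con)
  body <- paste(counts$chrom, counts$pos, ".", counts$ref, counts$alt,
                ".", "PASS", ".", "AD",
                paste0(counts$g_ref, ",", counts$g_alt),
                paste0(counts$y_ref, ",", counts$y_alt), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a gene table
#'
#' Simplified tab-separated gene models with header gene_id, chrom, strand,
#' start, end, start_codon (all coordinates 1-based inclusive).
#'
#' @param path Input path.
#' @return Gene table data.frame.
#' @export
read_gene_table <- function(path) {
  df <- read.delim(path, colClasses = c(chrom = "character"))
  need <- c("gene_id", "chrom", "strand", "start", "end", "start_codon")
  if (!all(need %in% names(df)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' Read gene models from a GFF3 file
#'
#' Imports gene, exon and (when present) start_codon or CDS features via
#' rtracklayer. The start-codon position falls back to the 5'-most CDS
#' boundary when no explicit start_codon feature exists, and to the gene
#' boundary when there is no CDS either.
#'
#' @param path GFF3 file.
#' @return List with `genes` (gene_id, chrom, strand, start, end,
#'   start_codon) and `exons` (gene_id, start, end).
#' @export
read_gff_genes <- function(path) {
  gff <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gff)
  ty <- tolower(as.character(md$type))
  parent_id <- function(x) sub("^[^:]*:", "", x)

  gidx <- which(ty == "gene")
  if (length(gidx) == 0) stop("no gene features in ", path)
  genes <- data.frame(
    gene_id = as.character(md$ID[gidx]),
    chrom = as.character(GenomicRanges::seqnames(gff)[gidx]),
    strand = as.character(GenomicRanges::strand(gff)[gidx]),
    start = GenomicRanges::start(gff)[gidx],
    end = GenomicRanges::end(gff)[gidx])
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"

  feature_parent <- function(i) {
    p <- if (!is.null(md$Parent)) unlist(md$Parent[i]) else NULL
    if (length(p) == 0 && !is.null(md$gene_id)) p <- md$gene_id[i]
    if (length(p) == 0) NA_character_ else parent_id(p[1])
  }
  # map transcript-level parents back to genes where needed
  tx_parent <- local({
    tidx <- which(ty %in% c("mrna", "transcript"))
    setNames(vapply(tidx, feature_parent, character(1)),
             as.character(md$ID[tidx]))
  })
  to_gene <- function(p) {
    p <- parent_id(p)
    if (p %in% genes$gene_id) p
    else if (p %in% names(tx_parent)) tx_parent[[p]]
    else NA_character_
  }

  start_codon <- setNames(rep(NA_real_, nrow(genes)), genes$gene_id)
  scidx <- which(ty == "start_codon")
  for (i in scidx) {
    g <- to_gene(feature_parent(i))
    if (!is.na(g))
      start_codon[g] <- if (genes$strand[genes$gene_id == g] == "+")
        GenomicRanges::start(gff)[i] else GenomicRanges::end(gff)[i]
  }
  cidx <- which(ty == "cds")
  for (i in cidx) {
    g <- to_gene(feature_parent(i))
    if (is.na(g) || !is.na(start_codon[g]) && length(scidx) > 0) next
    plus <- genes$strand[genes$gene_id == g] == "+"
    cand <- if (plus) GenomicRanges::start(gff)[i] else GenomicRanges::end(gff)[i]
    cur <- start_codon[g]
    start_codon[g] <- if (is.na(cur)) cand
      else if (plus) min(cur, cand) else max(cur, cand)
  }
  miss <- is.na(start_codon)
  start_codon[miss] <- ifelse(genes$strand[miss] == "+",
                              genes$start[miss], genes$end[miss])
  genes$start_codon <- unname(start_codon[genes$gene_id])

  eidx <- which(ty == "exon")
  exons <- data.frame(
    gene_id = vapply(eidx, function(i) {
      g <- to_gene(feature_parent(i)); if (is.na(g)) "" else g
    }, character(1)),
    start = GenomicRanges::start(gff)[eidx],
    end = GenomicRanges::end(gff)[eidx])
  exons <- exons[nzchar(exons$gene_id), , drop = FALSE]
  list(genes = genes, exons = exons)
}

#' Write a window profile / candidate regions
#'
#' The profile is tab-separated (chrom, start, end, mid, g_index, y_index,
#' delta, n_units, threshold); regions are written as BED3+ (0-based
#' half-open starts) with peak_delta and peak_pos columns.
#'
#' @param profile,regions Mapping outputs from [map_bsa()].
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  out <- data.frame(chrom = profile$chrom, start = profile$win_start,
                    end = profile$win_end, mid = profile$midpoint,
                    g_index = profile$g_index_mean,
                    y_index = profile$y_index_mean,
                    delta = profile$delta, n_units = profile$n_units,
                    threshold = profile$threshold)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
write_regions_bed <- function(regions, path) {
  out <- data.frame(chrom = regions$chrom, start = regions$start - 1,
                    end = regions$end,
                    name = sprintf("region_%d", seq_len(nrow(regions))),
                    peak_delta = regions$peak_delta,
                    peak_pos = regions$peak_pos)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
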