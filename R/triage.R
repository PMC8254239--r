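#' Candidate region record and span
#'
#' `candidate_region()` builds a single candidate-region record (1-based
#' inclusive internal coordinates); `region_span_mb()` reports its span as
#' the simple boundary difference in Mb, the convention used when a region
#' is quoted by its rounded Mb boundaries (3.08-3.42 Mb spans 0.34 Mb).
#'
#' @param chrom Chromosome name.
#' @param start,end Region boundaries in bp, `start < end`.
#' @param peak_delta,peak_pos,n_windows,n_sites Optional mapping metadata.
#' @return One-row data.frame for `candidate_region()`; numeric Mb span for
#'   `region_span_mb()`.
#' @export
#' @examples
#' region_span_mb(candidate_region("D10", 3.08e6, 3.42e6))  # 0.34
candidate_region <- function(chrom, start, end, peak_delta = NA_real_,
                             peak_pos = NA_real_, n_windows = NA_integer_,
                             n_sites = NA_integer_) {
  if (start >= end) stop("region start must be < end")
  data.frame(chrom = chrom, start = start, end = end,
             peak_delta = peak_delta, peak_pos = peak_pos,
             n_windows = n_windows, n_sites = n_sites)
}

#' @rdname candidate_region
#' @param region A region data.frame with `start` and `end` columns.
#' @export
region_span_mb <- function(region) {
  (region$end - region$start) / 1e6
}

#' Protein length encoded by an open reading frame
#'
#' An ORF of L bp including its stop codon encodes L/3 - 1 amino acids.
#'
#' @param orf_bp ORF length in bp, a positive multiple of 3 (>= 6 so that at
#'   least one codon precedes the stop).
#' @return Number of encoded amino acids.
#' @export
#' @examples
#' orf_protein_length(690)  # 229
orf_protein_length <- function(orf_bp) {
  if (any(orf_bp < 6) || any(orf_bp %% 3 != 0))
    stop("ORF length must be a multiple of 3 and >= 6 bp")
  orf_bp / 3 - 1
}

#' Genes overlapping candidate regions
#'
#' A gene belongs to a region when its interval overlaps the region by at
#' least 1 bp (both 1-based inclusive). Overlap is computed with
#' GenomicRanges. Genes on chromosomes absent from the region set are
#' skipped with a message.
#'
#' @param regions data.frame with chrom, start, end (e.g. from
#'   [call_regions()]).
#' @param genes Gene table: data.frame with gene_id, chrom, start, end.
#' @return List with `genes` (data.frame region_id, gene_id) and `summary`
#'   (region_id, chrom, start, end, n_genes).
#' @export
genes_in_regions <- function(regions, genes) {
  off_chrom <- !genes$chrom %in% unique(regions$chrom)
  if (any(off_chrom))
    message(sum(off_chrom),
            " gene(s) on chromosomes absent from the region set were skipped")
  genes_kept <- genes[!off_chrom, , drop = FALSE]
  if (nrow(regions) == 0 || nrow(genes_kept) == 0) {
    hits <- data.frame(region_id = integer(), gene_id = character())
  } else {
    gr_regions <- GenomicRanges::GRanges(
      regions$chrom, IRanges::IRanges(regions$start, regions$end))
    gr_genes <- GenomicRanges::GRanges(
      genes_kept$chrom, IRanges::IRanges(genes_kept$start, genes_kept$end))
    ov <- GenomicRanges::findOverlaps(gr_regions, gr_genes, minoverlap = 1L)
    hits <- data.frame(region_id = S4Vectors::queryHits(ov),
                       gene_id = genes_kept$gene_id[S4Vectors::subjectHits(ov)])
  }
  summary <- data.frame(region_id = seq_len(nrow(regions)),
                        chrom = regions$chrom, start = regions$start,
                        end = regions$end,
                        n_genes = tabulate(hits$region_id, nrow(regions)))
  list(genes = hits, summary = summary)
}

#' Signed offset of a position from a gene's start codon
#'
#' Offset 0 is the first base of the start codon; positions 5' of the start
#' codon on the coding strand are negative. On the + strand the offset is
#' `pos - start_codon_pos`; on the - strand it is `start_codon_pos - pos`.
#'
#' @param pos Genomic position (bp, 1-based), vectorised.
#' @param start_codon_pos Position of the first base of the ATG.
#' @param strand `"+"` or `"-"`.
#' @return Signed offset(s) in bp.
#' @export
#' @examples
#' offset_from_start_codon(3330215, 3330532, "+")  # -317
offset_from_start_codon <- function(pos, start_codon_pos, strand = "+") {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  ifelse(strand == "+", pos - start_codon_pos, start_codon_pos - pos)
}

#' Classify a SNP's location relative to gene models
#'
#' Location classes, in priority order when a position falls inside a gene:
#' `exonic` (inside an exon at/after the start codon on the coding strand),
#' `five_prime_utr` (inside the gene, 5' of the start codon), `intronic`
#' (inside the gene but neither). Outside all genes the position is
#' `upstream` when it lies within `upstream_window` bp 5' of at least one
#' gene (strand-aware), otherwise `intergenic`. `upstream_of` always lists
#' ALL genes whose upstream window contains the position, regardless of the
#' class assigned. When no exon intervals are supplied the gene body at and
#' after the start codon is treated as exonic.
#'
#' @param chrom,pos SNP location.
#' @param genes Gene table: gene_id, chrom, strand, start, end,
#'   start_codon (bp of the A of ATG).
#' @param exons Optional exon table: gene_id, start, end.
#' @param upstream_window Upstream window length in bp (default 1000).
#' @param ref,alt Optional alleles carried through to the output.
#' @return One-row data.frame: chrom, pos, ref, alt, location_class,
#'   gene_id (host or nearest upstream gene), offset_from_start_codon, and
#'   `upstream_of` (comma-separated gene ids, "" if none).
#' @export
classify_snp <- function(chrom, pos, genes, exons = NULL,
                         upstream_window = 1000,
                         ref = NA_character_, alt = NA_character_) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]

  up_of <- character(0)
  if (nrow(g) > 0) {
    up_start <- ifelse(g$strand == "+", g$start - upstream_window, g$end + 1)
    up_end <- ifelse(g$strand == "+", g$start - 1, g$end + upstream_window)
    up_of <- g$gene_id[pos >= up_start & pos <= up_end]
  }

  host <- g[nrow(g) > 0 & pos >= g$start & pos <= g$end, , drop = FALSE]
  location <- "intergenic"
  gene_id <- NA_character_
  offset <- NA_real_

  if (nrow(host) > 0) {
    cls <- vapply(seq_len(nrow(host)), function(i) {
      h <- host[i, ]
      off <- offset_from_start_codon(pos, h$start_codon, h$strand)
      if (off < 0) return("five_prime_utr")
      if (is.null(exons)) return("exonic")
      ex <- exons[exons$gene_id == h$gene_id, , drop = FALSE]
      if (nrow(ex) == 0) return("exonic")
      if (any(pos >= ex$start & pos <= ex$end)) "exonic" else "intronic"
    }, character(1))
    pick <- order(match(cls, c("exonic", "five_prime_utr", "intronic")))[1]
    location <- cls[pick]
    gene_id <- host$gene_id[pick]
    offset <- offset_from_start_codon(pos, host$start_codon[pick],
                                      host$strand[pick])
  } else if (length(up_of) > 0) {
    location <- "upstream"
    nearest <- g[match(up_of, g$gene_id), , drop = FALSE]
    d <- abs(offset_from_start_codon(pos, nearest$start_codon,
                                     nearest$strand))
    gene_id <- nearest$gene_id[which.min(d)]
    offset <- offset_from_start_codon(
      pos, nearest$start_codon[which.min(d)], nearest$strand[which.min(d)])
  }

  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             location_class = location, gene_id = gene_id,
             offset_from_start_codon = offset,
             upstream_of = paste(up_of, collapse = ","))
}

#' Zygosity call from pooled allele counts
#'
#' A site is called homozygous in a bulk when its alt-read fraction is at
#' least `hom_threshold` or at most `1 - hom_threshold` with depth at least
#' `min_depth`; otherwise heterozygous. Below `min_depth` the call is `NA`.
#'
#' @param alt,ref Read counts (vectorised).
#' @param hom_threshold Fraction above/below which a call is homozygous.
#' @param min_depth Minimum depth for a call.
#' @return Character vector of `"hom"`, `"het"`, `NA`.
#' @export
call_zygosity <- function(alt, ref, hom_threshold = 0.9, min_depth = 10) {
  depth <- alt + ref
  frac <- ifelse(depth > 0, alt / depth, NA_real_)
  # compare both tails as ">= threshold" so 1/10 vs 0.9 is not lost to
  # floating-point subtraction
  ifelse(depth < min_depth, NA_character_,
         ifelse(frac >= hom_threshold | (1 - frac) >= hom_threshold,
                "hom", "het"))
}

#' Triage candidate regulatory SNPs under a recessive model
#'
#' Applies two exclusion rules to a set of annotated candidate SNPs:
#'
#' * **R1 (recessive zygosity):** a SNP heterozygous in the mutant-phenotype
#'   (Y) bulk cannot be the causal variant of a recessive trait, since
#'   affected individuals must be homozygous; excluded.
#' * **R2 (shared upstream element):** a SNP lying upstream of two or more
#'   genes whose expression changes in DISCORDANT directions (one up, one
#'   down) is excluded: a single shared cis element cannot explain opposite
#'   changes. Genes with direction `"ns"` never trigger exclusion.
#'
#' @param snps data.frame with at least `snp_id`, `zygosity_y`
#'   (`"hom"`/`"het"`) and `upstream_of` (comma-separated gene ids, "" if
#'   none), e.g. rows built with [classify_snp()].
#' @param expression_directions Named character vector mapping gene_id to
#'   `"up"`, `"down"` or `"ns"`. An R2-relevant gene without a direction is
#'   an error.
#' @return The input with logical columns `excluded_r1`, `excluded_r2`,
#'   `retained` and a `reasons` column (comma-separated rule codes).
#' @export
triage_snps <- function(snps, expression_directions) {
  stopifnot(all(c("snp_id", "zygosity_y", "upstream_of") %in% names(snps)))
  bad_dir <- setdiff(unique(expression_directions), c("up", "down", "ns"))
  if (length(bad_dir) > 0)
    stop("expression directions must be up/down/ns; got: ",
         paste(bad_dir, collapse = ", "))

  r1 <- !is.na(snps$zygosity_y) & snps$zygosity_y == "het"
  r2 <- vapply(seq_len(nrow(snps)), function(i) {
    gs <- strsplit(snps$upstream_of[i], ",", fixed = TRUE)[[1]]
    gs <- gs[nzchar(gs)]
    if (length(gs) < 2) return(FALSE)
    missing <- setdiff(gs, names(expression_directions))
    if (length(missing) > 0)
      stop("no expression direction provided for gene '", missing[1], "'")
    dirs <- expression_directions[gs]
    any(dirs == "up") && any(dirs == "down")
  }, logical(1))

  snps$excluded_r1 <- r1
  snps$excluded_r2 <- r2
  snps$retained <- !r1 & !r2
  snps$reasons <- vapply(seq_len(nrow(snps)), function(i)
    paste(c("R1", "R2")[c(r1[i], r2[i])], collapse = ","), character(1))
  snps
}
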