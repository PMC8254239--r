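#' Run the BSA-seq mapping pipeline end to end
#'
#' Executes the stages in order — read counts, block aggregation, sliding
#' windows, delta, thresholds, region calling, and (when a gene annotation
#' is supplied) region-gene intersection — and writes the artifacts under
#' `out_prefix`: `<prefix>_profile.tsv`, `<prefix>_regions.bed`,
#' `<prefix>_regions.tsv`, optionally `<prefix>_genes.tsv`, and a
#' reproducibility log `<prefix>_run.json` holding every parameter, the
#' seed and the input checksum. Identical config + inputs give
#' byte-identical outputs. Any stage failure aborts with the stage name.
#'
#' @param counts A count table data.frame or a path readable by
#'   [read_counts()].
#' @param out_prefix Output path prefix.
#' @param chrom_lengths Optional named chromosome lengths (bp).
#' @param genes Optional gene table (data.frame or TSV/GFF3 path).
#' @param window_bp,step_bp,min_block_depth,min_units,min_windows,alpha,n_sim,threshold,pool_size_g,pool_size_y
#'   Mapping parameters, see [map_bsa()].
#' @param seed Seed driving the threshold simulation.
#' @return Invisibly, a list with `map` (the [map_bsa()] result), `genes`
#'   (or NULL) and `files` (paths written).
#' @export
run_bsa_pipeline <- function(counts, out_prefix, chrom_lengths = NULL,
                             genes = NULL,
                             window_bp = 1e6, step_bp = 1e4,
                             min_block_depth = 20, min_units = 3,
                             min_windows = 3, alpha = 0.05, n_sim = 10000,
                             threshold = NULL, pool_size_g = 40,
                             pool_size_y = 40, seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  input_path <- if (is.character(counts)) counts else NA_character_
  counts <- stage("read_counts",
                  if (is.character(counts)) read_counts(counts) else counts)
  if (nrow(counts) == 0)
    warning("empty count table: writing empty outputs")

  genes_tbl <- NULL
  if (!is.null(genes)) {
    genes_tbl <- stage("read_genes", {
      if (is.character(genes)) {
        if (grepl("\\.gff3?(\\.gz)?$", genes)) read_gff_genes(genes)$genes
        else read_gene_table(genes)
      } else genes
    })
  }

  res <- stage("map", map_bsa(
    counts, chrom_lengths = chrom_lengths, window_bp = window_bp,
    step_bp = step_bp, min_block_depth = min_block_depth,
    min_units = min_units, min_windows = min_windows, alpha = alpha,
    n_sim = n_sim, threshold = threshold, pool_size_g = pool_size_g,
    pool_size_y = pool_size_y, seed = seed))

  gene_hits <- NULL
  if (!is.null(genes_tbl) && nrow(res$regions) > 0)
    gene_hits <- stage("genes_in_regions",
                       suppressMessages(genes_in_regions(res$regions, genes_tbl)))

  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  files <- c(profile = paste0(out_prefix, "_profile.tsv"),
             regions_bed = paste0(out_prefix, "_regions.bed"),
             regions = paste0(out_prefix, "_regions.tsv"),
             log = paste0(out_prefix, "_run.json"))
  stage("write_outputs", {
    write_profile(res$profile, files[["profile"]])
    write_regions_bed(res$regions, files[["regions_bed"]])
    write.table(res$regions, files[["regions"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(gene_hits)) {
      files <- c(files, genes = paste0(out_prefix, "_genes.tsv"))
      merged <- merge(gene_hits$genes, gene_hits$summary[c("region_id",
                        "chrom", "start", "end")], by = "region_id")
      write.table(merged, paste0(out_prefix, "_genes.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    log <- list(tool = "bsamapr",
                version = as.character(packageVersion("bsamapr")),
                input = input_path,
                input_md5 = if (is.na(input_path)) NA
                            else unname(tools::md5sum(input_path)),
                n_sites = nrow(counts),
                n_skipped = attr(counts, "n_skipped") %||% 0L,
                params = res$params,
                n_regions = nrow(res$regions))
    writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, null = "null",
                                na = "null"), files[["log"]])
  })
  invisible(list(map = res, genes = gene_hits, files = files))
}
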