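#' Configure an F2 pooled-sequencing simulation
#'
#' Builds and validates the parameter set for simulating an F2 population
#' derived from two inbred parents, segregating for a single fully recessive
#' locus, together with phenotype-based bulks and pooled short-read allele
#' counts. The defaults describe the study design the package targets: an F2
#' of 967 seedlings scored for a recessive leaf-colour locus, bulks of 40
#' mutant-phenotype and 40 wild-phenotype individuals, and roughly 30x
#' per-bulk sequencing depth on a 60 Mb chromosome with an informative marker
#' every 10 kb.
#'
#' @param n_individuals Number of F2 individuals.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param marker_spacing Distance in bp between informative markers; markers
#'   are placed at `spacing, 2*spacing, ...` along each chromosome and the
#'   causal position is always included as a marker.
#' @param causal_chrom,causal_pos Location of the causal locus. Set
#'   `causal_chrom = NULL` for a null simulation with no causal locus, in
#'   which case phenotypes are drawn independently of genotype with
#'   P(mutant) = 1/4.
#' @param recomb_rate Recombination rate in cM per Mb; crossovers are laid
#'   down as a Poisson process without interference.
#' @param pool_size_green,pool_size_yellow Number of wild-phenotype (green)
#'   and mutant-phenotype (yellow) individuals pooled into each bulk.
#' @param mean_depth Mean per-site per-bulk read depth. Depth is Poisson
#'   distributed unless `fixed_depth = TRUE`, in which case every site gets
#'   exactly `round(mean_depth)` reads (useful for deterministic tests).
#' @param seq_error Per-read probability of reporting the wrong allele;
#'   must lie in \[0, 0.5).
#' @param misclass_prob Probability that an individual's phenotype is
#'   recorded as the wrong class. Defaults to 0 (full penetrance, clean
#'   scoring).
#' @param fixed_depth Logical; see `mean_depth`.
#' @param seed Integer seed from which all per-stage seeds are derived.
#'
#' @return An object of class `f2_sim_config`.
#' @export
#' @examples
#' cfg <- f2_sim_config(n_individuals = 200, chrom_lengths = c(chr1 = 5e6),
#'                      causal_chrom = "chr1", causal_pos = 2e6, seed = 7)
f2_sim_config <- function(n_individuals = 967,
                          chrom_lengths = c(D10 = 60e6),
                          marker_spacing = 10e3,
                          causal_chrom = "D10",
                          causal_pos = 3.3e6,
                          recomb_rate = 1,
                          pool_size_green = 40,
                          pool_size_yellow = 40,
                          mean_depth = 30,
                          seq_error = 0.005,
                          misclass_prob = 0,
                          fixed_depth = FALSE,
                          seed = 1L) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector of chromosome lengths (bp)")
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1 bp")
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (marker_spacing < 1) stop("marker_spacing must be >= 1 bp")
  if (!is.null(causal_chrom)) {
    if (!causal_chrom %in% names(chrom_lengths))
      stop("causal_chrom '", causal_chrom, "' is not in chrom_lengths")
    if (causal_pos < 1 || causal_pos > chrom_lengths[[causal_chrom]])
      stop("causal_pos ", causal_pos, " is outside chromosome '",
           causal_chrom, "' (length ", chrom_lengths[[causal_chrom]], ")")
  }
  if (recomb_rate < 0) stop("recomb_rate must be >= 0")
  if (pool_size_green < 1 || pool_size_yellow < 1)
    stop("pool sizes must be >= 1")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (seq_error < 0 || seq_error >= 0.5)
    stop("seq_error must lie in [0, 0.5); got ", seq_error)
  if (misclass_prob < 0 || misclass_prob >= 1)
    stop("misclass_prob must lie in [0, 1)")

  # marker map: spacing grid per chromosome, causal position always included
  markers <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    pos <- if (marker_spacing > chrom_lengths[[ch]]) numeric(0)
           else seq(marker_spacing, chrom_lengths[[ch]], by = marker_spacing)
    if (!is.null(causal_chrom) && ch == causal_chrom)
      pos <- sort(unique(c(pos, causal_pos)))
    if (length(pos) == 0)
      stop("chromosome '", ch, "' has zero markers at spacing ",
           marker_spacing, " bp")
    data.frame(chrom = ch, pos = pos)
  }))
  rownames(markers) <- NULL

  structure(list(
    n_individuals = as.integer(n_individuals),
    chrom_lengths = chrom_lengths,
    marker_spacing = marker_spacing,
    causal_chrom = causal_chrom,
    causal_pos = if (is.null(causal_chrom)) NA_real_ else causal_pos,
    recomb_rate = recomb_rate,
    pool_size_green = as.integer(pool_size_green),
    pool_size_yellow = as.integer(pool_size_yellow),
    mean_depth = mean_depth,
    seq_error = seq_error,
    misclass_prob = misclass_prob,
    fixed_depth = isTRUE(fixed_depth),
    seed = as.integer(seed),
    markers = markers
  ), class = "f2_sim_config")
}

#' @export
print.f2_sim_config <- function(x, ...) {
  cat("F2 pooled-sequencing simulation config\n")
  cat("  individuals:", x$n_individuals,
      " bulks (G/Y):", x$pool_size_green, "/", x$pool_size_yellow, "\n")
  cat("  chromosomes:", paste0(names(x$chrom_lengths), " (",
      x$chrom_lengths / 1e6, " Mb)", collapse = ", "), "\n")
  if (is.null(x$causal_chrom)) {
    cat("  causal locus: none (null simulation)\n")
  } else {
    cat("  causal locus:", x$causal_chrom, "at", x$causal_pos, "bp\n")
  }
  cat("  markers:", nrow(x$markers), " depth:", x$mean_depth,
      " seq_error:", x$seq_error, " seed:", x$seed, "\n")
  invisible(x)
}

# Simulate n gametes of an F1 along one chromosome.
#
# positions: marker positions (bp, sorted); chrom_len: bp; rate: cM/Mb.
# Each gamete starts on a random parental haplotype and switches at crossover
# points drawn as a Poisson process (no interference). Returns an n x m 0/1
# matrix of mutant-parent allele indicators.
sim_gametes <- function(positions, chrom_len, rate, n) {
  m <- length(positions)
  lambda <- rate / 100 * chrom_len / 1e6   # expected crossovers per gamete
  n_cx <- rpois(n, lambda)
  start <- rbinom(n, 1L, 0.5)
  out <- matrix(rep(start, m), nrow = n, ncol = m)
  hot <- which(n_cx > 0L)
  for (i in hot) {
    cx <- sort(runif(n_cx[i], min = 0, max = chrom_len))
    out[i, ] <- (start[i] + findInterval(positions, cx)) %% 2L
  }
  out
}

#' Simulate an F2 population
#'
#' Draws genotypes for every F2 individual at every marker by forming each
#' individual from two independent F1 gametes; gametes recombine as a Poisson
#' crossover process along each chromosome. Phenotypes follow a fully
#' penetrant recessive model: an individual shows the mutant (yellow)
#' phenotype iff it carries two copies of the mutant-parent allele at the
#' causal locus (subject to `misclass_prob`).
#'
#' @param config An [f2_sim_config()].
#' @return An object of class `f2_sim_truth`: a list with `markers`
#'   (data.frame chrom/pos), `genotypes` (individuals x markers integer
#'   matrix of mutant-allele copies 0/1/2), `phenotypes` (character,
#'   `"green"`/`"yellow"`), `causal_chrom`, `causal_pos` and the `config`.
#' @export
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "f2_sim_config"))
  n <- config$n_individuals
  markers <- config$markers

  set.seed(stage_seed(config$seed, "gametes"))
  geno <- matrix(0L, nrow = n, ncol = nrow(markers))
  for (ch in names(config$chrom_lengths)) {
    idx <- which(markers$chrom == ch)
    gam <- sim_gametes(markers$pos[idx], config$chrom_lengths[[ch]],
                       config$recomb_rate, 2L * n)
    geno[, idx] <- gam[seq_len(n), , drop = FALSE] +
      gam[n + seq_len(n), , drop = FALSE]
  }
  colnames(geno) <- paste(markers$chrom, markers$pos, sep = ":")

  set.seed(stage_seed(config$seed, "phenotype"))
  if (is.null(config$causal_chrom)) {
    yellow <- rbinom(n, 1L, 0.25) == 1L
  } else {
    causal_idx <- which(markers$chrom == config$causal_chrom &
                          markers$pos == config$causal_pos)
    yellow <- geno[, causal_idx] == 2L
    if (config$misclass_prob > 0) {
      flip <- rbinom(n, 1L, config$misclass_prob) == 1L
      yellow <- xor(yellow, flip)
    }
  }

  structure(list(
    markers = markers,
    genotypes = geno,
    phenotypes = ifelse(yellow, "yellow", "green"),
    causal_chrom = config$causal_chrom,
    causal_pos = config$causal_pos,
    config = config
  ), class = "f2_sim_truth")
}

#' Form phenotype-based bulks and compute true bulk allele frequencies
#'
#' Samples `pool_size_yellow` mutant-phenotype and `pool_size_green`
#' wild-phenotype individuals without replacement and computes, at every
#' marker, each bulk's true mutant-allele frequency
#' (sum of genotype copies) / (2 * pool size).
#'
#' @param truth An [simulate_f2()] result.
#' @param config The same config used to simulate `truth`.
#' @return A list with `freqs` (data.frame chrom, pos, g_freq, y_freq),
#'   `g_members` and `y_members` (row indices of pooled individuals).
#' @export
make_bulks <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "f2_sim_truth"))
  green_ids <- which(truth$phenotypes == "green")
  yellow_ids <- which(truth$phenotypes == "yellow")
  if (length(green_ids) < config$pool_size_green)
    stop("not enough green individuals: need ", config$pool_size_green,
         ", have ", length(green_ids))
  if (length(yellow_ids) < config$pool_size_yellow)
    stop("not enough yellow individuals: need ", config$pool_size_yellow,
         ", have ", length(yellow_ids))

  set.seed(stage_seed(config$seed, "bulks"))
  g_members <- sort(sample(green_ids, config$pool_size_green))
  y_members <- sort(sample(yellow_ids, config$pool_size_yellow))

  g_freq <- colSums(truth$genotypes[g_members, , drop = FALSE]) /
    (2 * config$pool_size_green)
  y_freq <- colSums(truth$genotypes[y_members, , drop = FALSE]) /
    (2 * config$pool_size_yellow)

  list(freqs = data.frame(chrom = truth$markers$chrom,
                          pos = truth$markers$pos,
                          g_freq = unname(g_freq),
                          y_freq = unname(y_freq)),
       g_members = g_members, y_members = y_members)
}

#' Sample pooled read counts from bulk allele frequencies
#'
#' Emulates pooled whole-genome sequencing of the two bulks. Per site and
#' bulk, total depth is Poisson(`mean_depth`) (or fixed), and mutant-allele
#' reads are Binomial(depth, f(1-e) + (1-f)e) where `f` is the bulk's true
#' allele frequency and `e` the per-read error rate. Reference and mutant
#' bases are drawn once per site (distinct by construction).
#'
#' @param bulks A [make_bulks()] result (or any data.frame with columns
#'   chrom, pos, g_freq, y_freq passed as `bulks$freqs`).
#' @param config An [f2_sim_config()].
#' @return A count table: data.frame with columns chrom, pos, ref, alt,
#'   g_ref, g_alt, y_ref, y_alt. Deterministic under the config seed.
#' @export
simulate_read_counts <- function(bulks, config) {
  freqs <- if (is.data.frame(bulks)) bulks else bulks$freqs
  stopifnot(all(c("chrom", "pos", "g_freq", "y_freq") %in% names(freqs)))
  if (any(freqs$g_freq < 0 | freqs$g_freq > 1 |
            freqs$y_freq < 0 | freqs$y_freq > 1))
    stop("bulk allele frequencies must lie in [0, 1]")
  m <- nrow(freqs)
  e <- config$seq_error

  set.seed(stage_seed(config$seed, "counts"))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

  depth_g <- if (config$fixed_depth) rep(as.integer(round(config$mean_depth)), m)
             else rpois(m, config$mean_depth)
  depth_y <- if (config$fixed_depth) rep(as.integer(round(config$mean_depth)), m)
             else rpois(m, config$mean_depth)
  p_g <- freqs$g_freq * (1 - e) + (1 - freqs$g_freq) * e
  p_y <- freqs$y_freq * (1 - e) + (1 - freqs$y_freq) * e
  g_alt <- rbinom(m, depth_g, p_g)
  y_alt <- rbinom(m, depth_y, p_y)

  data.frame(chrom = freqs$chrom, pos = freqs$pos,
             ref = unname(ref), alt = unname(alt),
             g_ref = depth_g - g_alt, g_alt = g_alt,
             y_ref = depth_y - y_alt, y_alt = y_alt)
}

#' Simulate a complete BSA-seq dataset with ground truth
#'
#' Convenience wrapper chaining [simulate_f2()], [make_bulks()] and
#' [simulate_read_counts()].
#'
#' @param config An [f2_sim_config()].
#' @return List with `truth`, `bulks` and `counts`.
#' @export
simulate_bsa_dataset <- function(config) {
  truth <- simulate_f2(config)
  bulks <- make_bulks(truth, config)
  counts <- simulate_read_counts(bulks, config)
  list(truth = truth, bulks = bulks, counts = counts)
}

#' Write / read simulation ground truth
#'
#' The truth file is tab-separated: a first comment line records the causal
#' locus, then a genotype matrix (individuals x markers, columns named
#' `chrom:pos`) with a final `phenotype` column. Truth and counts live in
#' separate files so the mapping stages never see the truth.
#'
#' @param truth A [simulate_f2()] result.
#' @param path Output (or input) file path.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  causal <- if (is.null(truth$causal_chrom)) "none\tNA"
            else paste(truth$causal_chrom, truth$causal_pos, sep = "\t")
  writeLines(paste0("#causal\t", causal), con)
  df <- as.data.frame(truth$genotypes)
  df$phenotype <- truth$phenotypes
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  first <- readLines(path, n = 1L)
  parts <- strsplit(sub("^#causal\t", "", first), "\t")[[1]]
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  pheno <- df$phenotype
  geno <- as.matrix(df[, setdiff(names(df), "phenotype"), drop = FALSE])
  ids <- strsplit(colnames(geno), ":", fixed = TRUE)
  markers <- data.frame(chrom = vapply(ids, `[`, "", 1L),
                        pos = as.numeric(vapply(ids, `[`, "", 2L)))
  structure(list(
    markers = markers, genotypes = geno, phenotypes = pheno,
    causal_chrom = if (parts[1] == "none") NULL else parts[1],
    causal_pos = suppressWarnings(as.numeric(parts[2])),
    config = NULL
  ), class = "f2_sim_truth")
}
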