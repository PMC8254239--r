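#' Per-site SNP-index
#'
#' The SNP-index at one site in one bulk is the proportion of aligned reads
#' carrying the variant (mutant-parent) allele: `alt_depth / total_depth`.
#' Sites with zero depth return `NA`.
#'
#' @param alt_depth,total_depth Non-negative read counts (vectorised).
#' @return Numeric vector of fractions in \[0, 1\], `NA` where depth is 0.
#' @export
#' @examples
#' site_snp_index(7, 20)   # 0.35
site_snp_index <- function(alt_depth, total_depth) {
  if (any(alt_depth < 0) || any(total_depth < 0))
    stop("read counts must be non-negative")
  if (any(alt_depth > total_depth))
    stop("alt_depth exceeds total_depth")
  ifelse(total_depth == 0, NA_real_, alt_depth / total_depth)
}

#' Aggregate consecutive low-depth sites into depth blocks
#'
#' Scanning each chromosome left to right, consecutive sites are accumulated
#' into the current block until the summed read depth of BOTH bulks reaches
#' `min_block_depth`, at which point the block closes; a site that alone
#' meets the depth in both bulks forms its own block. A trailing run that
#' never reaches the depth is emitted with `complete = FALSE`. Block indices
#' are depth-weighted: summed alt reads over summed depth. Blocks never span
#' chromosomes.
#'
#' @param sites Count table (chrom, pos, g_ref, g_alt, y_ref, y_alt), sorted
#'   by chromosome then position.
#' @param min_block_depth Minimum summed depth per bulk to close a block.
#' @return data.frame of blocks: chrom, start, end, n_sites, per-bulk alt and
#'   depth sums, g_index, y_index, complete.
#' @export
aggregate_blocks <- function(sites, min_block_depth = 20) {
  if (min_block_depth <= 0) stop("min_block_depth must be > 0")
  if (nrow(sites) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_sites = integer(),
                      g_alt_sum = numeric(), g_depth_sum = numeric(),
                      y_alt_sum = numeric(), y_depth_sum = numeric(),
                      g_index = numeric(), y_index = numeric(),
                      complete = logical()))
  }
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (!identical(ord, seq_len(nrow(sites))) ||
        any(duplicated(sites[c("chrom", "pos")])))
    stop("sites must be sorted by (chrom, pos) without duplicates")

  g_depth <- sites$g_ref + sites$g_alt
  y_depth <- sites$y_ref + sites$y_alt
  n <- nrow(sites)
  # block id per site: accumulate per chromosome until both bulks reach depth
  block_id <- integer(n)
  complete_flag <- logical(0)
  k <- 0L
  for (ch in unique(sites$chrom)) {
    open <- FALSE
    g_d <- y_d <- 0
    for (i in which(sites$chrom == ch)) {
      if (!open) {
        k <- k + 1L
        open <- TRUE
        g_d <- y_d <- 0
      }
      block_id[i] <- k
      g_d <- g_d + g_depth[i]; y_d <- y_d + y_depth[i]
      if (g_d >= min_block_depth && y_d >= min_block_depth) {
        complete_flag[k] <- TRUE
        open <- FALSE
      }
    }
    if (open) complete_flag[k] <- FALSE  # trailing block never reached depth
  }
  f <- factor(block_id, levels = seq_len(k))
  g_a <- as.numeric(tapply(sites$g_alt, f, sum))
  g_d <- as.numeric(tapply(g_depth, f, sum))
  y_a <- as.numeric(tapply(sites$y_alt, f, sum))
  y_d <- as.numeric(tapply(y_depth, f, sum))
  data.frame(
    chrom = as.character(tapply(sites$chrom, f, `[`, 1L)),
    start = as.numeric(tapply(sites$pos, f, min)),
    end = as.numeric(tapply(sites$pos, f, max)),
    n_sites = as.integer(tabulate(block_id, k)),
    g_alt_sum = g_a, g_depth_sum = g_d,
    y_alt_sum = y_a, y_depth_sum = y_d,
    g_index = ifelse(g_d > 0, g_a / g_d, NA_real_),
    y_index = ifelse(y_d > 0, y_a / y_d, NA_real_),
    complete = complete_flag[seq_len(k)])
}

#' Sliding-window SNP-index profile along one chromosome
#'
#' Windows of `window_bp` start at 1, 1 + `step_bp`, 1 + 2 `step_bp`, ...
#' up to `chrom_length`; terminal windows are truncated at the chromosome end
#' and flagged. A unit (depth block or single site) belongs to a window when
#' its start position lies inside it. Window means are the unweighted means
#' of member-unit indices; windows with fewer than `min_units` informative
#' units report missing means.
#'
#' @param units data.frame of blocks ([aggregate_blocks()]) or sites; must
#'   have columns `g_index`, `y_index` and either `start` or `pos`, all on a
#'   single chromosome.
#' @param window_bp,step_bp Window length and step in bp.
#' @param chrom_length Chromosome length in bp.
#' @param min_units Minimum informative units per window.
#' @return data.frame of window points: chrom, win_start, win_end, midpoint,
#'   g_index_mean, y_index_mean, n_units, truncated.
#' @export
window_profile <- function(units, window_bp = 1e6, step_bp = 1e4,
                           chrom_length, min_units = 3) {
  if (chrom_length < 1) stop("chrom_length must be >= 1")
  if (!(window_bp >= step_bp && step_bp > 0))
    stop("need window_bp >= step_bp > 0")
  pos <- if ("start" %in% names(units)) units$start else units$pos
  chrom <- if (nrow(units) > 0 && "chrom" %in% names(units)) {
    u <- unique(units$chrom)
    if (length(u) > 1) stop("window_profile works on one chromosome at a time")
    u
  } else NA_character_

  keep <- !is.na(units$g_index) & !is.na(units$y_index)
  pos <- pos[keep]
  g <- units$g_index[keep]
  y <- units$y_index[keep]
  ord <- order(pos)
  pos <- pos[ord]; g <- g[ord]; y <- y[ord]

  win_start <- seq(1, chrom_length, by = step_bp)
  win_end <- pmin(win_start + window_bp - 1, chrom_length)
  cg <- c(0, cumsum(g))
  cy <- c(0, cumsum(y))
  lo <- findInterval(win_start - 1, pos) + 1L
  hi <- findInterval(win_end, pos)
  n_units <- pmax(hi - lo + 1L, 0L)
  g_mean <- ifelse(n_units > 0, (cg[hi + 1] - cg[lo]) / n_units, NA_real_)
  y_mean <- ifelse(n_units > 0, (cy[hi + 1] - cy[lo]) / n_units, NA_real_)
  # prefix-sum rounding can overshoot the [0,1] range by ~1e-16; clamp
  g_mean <- pmin(pmax(g_mean, 0), 1)
  y_mean <- pmin(pmax(y_mean, 0), 1)
  sparse <- n_units < min_units
  g_mean[sparse] <- NA_real_
  y_mean[sparse] <- NA_real_

  data.frame(chrom = chrom, win_start = win_start, win_end = win_end,
             midpoint = floor((win_start + win_end) / 2),
             g_index_mean = g_mean, y_index_mean = y_mean,
             n_units = n_units,
             truncated = win_end - win_start + 1 < window_bp)
}

#' Fill the delta-SNP-index column of a window profile
#'
#' Delta is the Y-bulk (mutant-phenotype) window mean minus the G-bulk
#' (wild-phenotype) window mean; missing whenever either mean is missing.
#' Under this sign convention a recessive causal locus produces a positive
#' peak (Y-bulk fixed for the mutant allele, G-bulk at 1/3).
#'
#' @param profile A [window_profile()] data.frame.
#' @return The profile with a `delta` column added.
#' @export
delta_profile <- function(profile) {
  profile$delta <- profile$y_index_mean - profile$g_index_mean
  profile
}

#' Null-simulation significance threshold for delta-SNP-index
#'
#' Simulates sites with no causal linkage: each bulk is a random sample of
#' F2 individuals, so its true allele frequency is Binomial(2 * pool size,
#' 1/2) / (2 * pool size) (the 1:2:1 genotype draw), bulks independent; read
#' counts are Binomial(depth, frequency). Returns the empirical
#' (1 - `alpha`) quantile of the simulated delta (y_index - g_index).
#'
#' @param pool_size_g,pool_size_y Bulk sizes (individuals).
#' @param depth Per-bulk read depth of the unit being thresholded.
#' @param alpha Upper tail probability.
#' @param n_sim Number of simulated null sites.
#' @param seed Optional seed for reproducibility.
#' @return A single threshold value.
#' @export
null_threshold <- function(pool_size_g = 40, pool_size_y = 40, depth,
                           alpha = 0.05, n_sim = 10000, seed = NULL) {
  if (pool_size_g < 1 || pool_size_y < 1 || depth < 1)
    stop("pool sizes and depth must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  f_g <- rbinom(n_sim, 2L * pool_size_g, 0.5) / (2 * pool_size_g)
  f_y <- rbinom(n_sim, 2L * pool_size_y, 0.5) / (2 * pool_size_y)
  g_idx <- rbinom(n_sim, depth, f_g) / depth
  y_idx <- rbinom(n_sim, depth, f_y) / depth
  unname(quantile(y_idx - g_idx, 1 - alpha))
}

#' Attach per-window null thresholds to a delta profile
#'
#' Each window's threshold is the [null_threshold()] quantile evaluated at
#' that window's median unit depth, where a unit's depth is the mean of the
#' two bulks' summed depths. Thresholds are cached per unique rounded depth.
#' Alternatively a fixed threshold can be supplied.
#'
#' @param profile A delta profile ([delta_profile()]).
#' @param units The units the profile was built from (needs depth columns
#'   `g_depth_sum`/`y_depth_sum` for blocks, or g_ref+g_alt etc. for sites).
#' @param pool_size_g,pool_size_y,alpha,n_sim,seed Passed to
#'   [null_threshold()].
#' @param threshold Optional fixed threshold overriding the simulation.
#' @return The profile with a `threshold` column.
#' @export
add_thresholds <- function(profile, units, pool_size_g = 40, pool_size_y = 40,
                           alpha = 0.05, n_sim = 10000, seed = NULL,
                           threshold = NULL) {
  if (!is.null(threshold)) {
    profile$threshold <- threshold
    return(profile)
  }
  if (!is.null(seed)) set.seed(seed)
  if (all(c("g_depth_sum", "y_depth_sum") %in% names(units))) {
    unit_depth <- (units$g_depth_sum + units$y_depth_sum) / 2
  } else {
    unit_depth <- (units$g_ref + units$g_alt + units$y_ref + units$y_alt) / 2
  }
  pos <- if ("start" %in% names(units)) units$start else units$pos
  keep <- !is.na(units$g_index) & !is.na(units$y_index)
  pos <- pos[keep]; unit_depth <- unit_depth[keep]
  ord <- order(pos); pos <- pos[ord]; unit_depth <- unit_depth[ord]

  lo <- findInterval(profile$win_start - 1, pos) + 1L
  hi <- findInterval(profile$win_end, pos)
  med_depth <- rep(NA_real_, nrow(profile))
  nz <- hi >= lo
  med_depth[nz] <- vapply(which(nz), function(i)
    round(median(unit_depth[lo[i]:hi[i]])), numeric(1))

  cache <- new.env(parent = emptyenv())
  profile$threshold <- vapply(med_depth, function(d) {
    if (is.na(d) || d < 1) return(NA_real_)
    key <- as.character(d)
    if (is.null(cache[[key]]))
      cache[[key]] <- null_threshold(pool_size_g, pool_size_y, d,
                                     alpha = alpha, n_sim = n_sim)
    cache[[key]]
  }, numeric(1))
  profile
}

#' Call candidate regions from a thresholded delta profile
#'
#' Maximal runs of consecutive windows whose delta exceeds their threshold
#' are merged into candidate regions; missing deltas or thresholds break a
#' run. Runs shorter than `min_windows` are dropped. The region spans from
#' the first window's start to the last window's end; the peak delta and its
#' window midpoint are recorded.
#'
#' @param profile Thresholded delta profile, sorted by window start within
#'   chromosome.
#' @param min_windows Minimum run length.
#' @param units Optional units table; when given, `n_sites` counts the units
#'   whose start lies inside each region.
#' @return data.frame of regions: chrom, start, end, peak_delta, peak_pos,
#'   n_windows, n_sites.
#' @export
call_regions <- function(profile, min_windows = 3, units = NULL) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_delta = numeric(),
                      peak_pos = numeric(), n_windows = integer(),
                      n_sites = integer())
  if (nrow(profile) == 0) return(empty)
  out <- list()
  for (ch in unique(profile$chrom)) {
    p <- profile[profile$chrom == ch, , drop = FALSE]
    p <- p[order(p$win_start), , drop = FALSE]
    ok <- !is.na(p$delta) & !is.na(p$threshold) & p$delta > p$threshold
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_windows)) {
      rows <- starts[j]:ends[j]
      peak <- rows[which.max(p$delta[rows])]
      n_sites <- if (is.null(units)) NA_integer_ else {
        upos <- if ("start" %in% names(units)) units$start else units$pos
        sum(units$chrom == ch & upos >= p$win_start[rows[1]] &
              upos <= p$win_end[rows[length(rows)]])
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = p$win_start[rows[1]],
        end = p$win_end[rows[length(rows)]],
        peak_delta = p$delta[peak], peak_pos = p$midpoint[peak],
        n_windows = length(rows), n_sites = n_sites)
    }
  }
  if (length(out) == 0) empty else do.call(rbind, out)
}

#' Run the full delta-SNP-index mapping on a count table
#'
#' Chains [aggregate_blocks()], [window_profile()], [delta_profile()],
#' [add_thresholds()] and [call_regions()] over every chromosome.
#'
#' @param counts Count table (chrom, pos, ref, alt, g_ref, g_alt, y_ref,
#'   y_alt).
#' @param chrom_lengths Named vector of chromosome lengths in bp. Lengths
#'   default to the last site position per chromosome when omitted.
#' @param window_bp,step_bp,min_block_depth,min_units,min_windows,alpha,n_sim
#'   Stage parameters; see the stage functions.
#' @param threshold Optional fixed delta threshold replacing the null
#'   simulation.
#' @param pool_size_g,pool_size_y Bulk sizes used by the null simulation.
#' @param seed Seed for the threshold simulation.
#' @return List of class `bsa_map`: `blocks`, `profile`, `regions`, `params`.
#' @export
map_bsa <- function(counts, chrom_lengths = NULL,
                    window_bp = 1e6, step_bp = 1e4, min_block_depth = 20,
                    min_units = 3, min_windows = 3, alpha = 0.05,
                    n_sim = 10000, threshold = NULL,
                    pool_size_g = 40, pool_size_y = 40, seed = NULL) {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(counts$pos, counts$chrom, max)
    chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  if (!is.null(seed)) set.seed(stage_seed(seed, "threshold"))
  blocks <- aggregate_blocks(counts, min_block_depth = min_block_depth)
  profiles <- lapply(unique(counts$chrom), function(ch) {
    b <- blocks[blocks$chrom == ch, , drop = FALSE]
    prof <- window_profile(b, window_bp = window_bp, step_bp = step_bp,
                           chrom_length = chrom_lengths[[ch]],
                           min_units = min_units)
    prof$chrom <- ch
    prof <- delta_profile(prof)
    add_thresholds(prof, b, pool_size_g = pool_size_g,
                   pool_size_y = pool_size_y, alpha = alpha, n_sim = n_sim,
                   threshold = threshold)
  })
  profile <- if (length(profiles) == 0) {
    data.frame(chrom = character(), win_start = numeric(),
               win_end = numeric(), midpoint = numeric(),
               g_index_mean = numeric(), y_index_mean = numeric(),
               n_units = integer(), truncated = logical(),
               delta = numeric(), threshold = numeric())
  } else do.call(rbind, profiles)
  regions <- call_regions(profile, min_windows = min_windows, units = blocks)
  structure(list(blocks = blocks, profile = profile, regions = regions,
                 params = list(window_bp = window_bp, step_bp = step_bp,
                               min_block_depth = min_block_depth,
                               min_units = min_units,
                               min_windows = min_windows, alpha = alpha,
                               n_sim = n_sim, threshold = threshold,
                               pool_size_g = pool_size_g,
                               pool_size_y = pool_size_y, seed = seed)),
            class = "bsa_map")
}

#' @export
print.bsa_map <- function(x, ...) {
  cat("BSA delta-SNP-index map\n")
  cat("  blocks:", nrow(x$blocks), " windows:", nrow(x$profile),
      " candidate regions:", nrow(x$regions), "\n")
  if (nrow(x$regions) > 0) {
    top <- x$regions[which.max(x$regions$peak_delta), ]
    cat(sprintf("  top region: %s:%.0f-%.0f (peak delta %.3f at %.0f)\n",
                top$chrom, top$start, top$end, top$peak_delta, top$peak_pos))
  }
  invisible(x)
}
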