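# Independent brute-force references used to check the vectorised
# implementations on small instances.

brute_window_profile <- function(units, window_bp, step_bp, chrom_length,
                                 min_units = 3) {
  pos <- if ("start" %in% names(units)) units$start else units$pos
  keep <- !is.na(units$g_index) & !is.na(units$y_index)
  starts <- seq(1, chrom_length, by = step_bp)
  rows <- lapply(starts, function(ws) {
    we <- min(ws + window_bp - 1, chrom_length)
    member <- which(keep & pos >= ws & pos <= we)
    n <- length(member)
    data.frame(win_start = ws, win_end = we,
               midpoint = floor((ws + we) / 2),
               g_index_mean = if (n >= min_units) mean(units$g_index[member]) else NA_real_,
               y_index_mean = if (n >= min_units) mean(units$y_index[member]) else NA_real_,
               n_units = n)
  })
  do.call(rbind, rows)
}

brute_call_regions <- function(profile, min_windows = 3) {
  ok <- !is.na(profile$delta) & !is.na(profile$threshold) &
    profile$delta > profile$threshold
  regions <- list()
  i <- 1
  while (i <= nrow(profile)) {
    if (ok[i]) {
      j <- i
      while (j < nrow(profile) && ok[j + 1] &&
               profile$chrom[j + 1] == profile$chrom[i]) j <- j + 1
      if (j - i + 1 >= min_windows) {
        run <- i:j
        peak <- run[which.max(profile$delta[run])]
        regions[[length(regions) + 1]] <- data.frame(
          chrom = profile$chrom[i], start = profile$win_start[i],
          end = profile$win_end[j], peak_delta = profile$delta[peak],
          peak_pos = profile$midpoint[peak], n_windows = j - i + 1)
      }
      i <- j + 1
    } else i <- i + 1
  }
  if (length(regions) == 0) NULL else do.call(rbind, regions)
}

brute_genes_in_regions <- function(regions, genes) {
  hits <- list()
  for (r in seq_len(nrow(regions))) {
    for (g in seq_len(nrow(genes))) {
      if (regions$chrom[r] == genes$chrom[g] &&
            genes$start[g] <= regions$end[r] &&
            genes$end[g] >= regions$start[r])
        hits[[length(hits) + 1]] <- data.frame(region_id = r,
                                               gene_id = genes$gene_id[g])
    }
  }
  if (length(hits) == 0) data.frame(region_id = integer(),
                                    gene_id = character())
  else do.call(rbind, hits)
}

# random small mapping instance for oracle-equivalence checks
random_map_instance <- function(max_sites = 50) {
  chrom_length <- sample(500:5000, 1)
  n <- sample(1:max_sites, 1)
  pos <- sort(sample(seq_len(chrom_length), n))
  units <- data.frame(chrom = "c1", pos = pos,
                      g_index = round(runif(n), 3),
                      y_index = round(runif(n), 3))
  window_bp <- sample(50:1000, 1)
  step_bp <- sample(seq_len(window_bp), 1)
  list(units = units, window_bp = window_bp, step_bp = step_bp,
       chrom_length = chrom_length,
       min_units = sample(1:3, 1), min_windows = sample(1:3, 1),
       threshold = round(runif(1, -0.5, 0.5), 2))
}
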