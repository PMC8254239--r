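#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct(target) - Ct(reference); ddCt is the mean dCt of
#' the mutant group minus the mean dCt of the wild-type group, and the fold
#' change of the mutant relative to wild type is 2^-ddCt. Significance is a
#' two-sided Student's t-test on the replicate dCt values (equal variances
#' by default, Welch optional).
#'
#' @param wt,mutant data.frames with columns `ct_target` and `ct_reference`
#'   (one row per biological replicate; at least 2 per group) and optionally
#'   `reference_gene`, which must be identical across all records.
#' @param gene Optional target-gene name carried into the result.
#' @param alpha Significance level for the direction call.
#' @param var_equal Equal-variance t-test (classic Student) when `TRUE`.
#' @return Object of class `ddct_result`: gene, fold_change, ddct, p_value,
#'   direction (`"up"`/`"down"`/`"ns"`), alpha.
#' @export
#' @examples
#' wt  <- data.frame(ct_target = c(24.1, 24.3, 24.0), ct_reference = 20)
#' mut <- data.frame(ct_target = c(26.2, 26.0, 26.3), ct_reference = 20)
#' ddct_fold_change(wt, mut, gene = "ABCI1")
ddct_fold_change <- function(wt, mutant, gene = NA_character_,
                             alpha = 0.05, var_equal = TRUE) {
  for (d in list(wt, mutant)) {
    if (!all(c("ct_target", "ct_reference") %in% names(d)))
      stop("each group needs ct_target and ct_reference columns")
    if (nrow(d) < 2) stop("need >= 2 replicates per group")
    if (any(d$ct_target <= 0) || any(d$ct_reference <= 0))
      stop("Ct values must be > 0")
  }
  refs <- c(wt$reference_gene, mutant$reference_gene)
  if (!is.null(refs) && length(unique(refs)) > 1)
    stop("all records must share the same reference gene; found: ",
         paste(unique(refs), collapse = ", "))

  dct_wt <- wt$ct_target - wt$ct_reference
  dct_mut <- mutant$ct_target - mutant$ct_reference
  ddct <- mean(dct_mut) - mean(dct_wt)
  fold <- 2^(-ddct)
  cmp <- group_compare(dct_wt, dct_mut, alpha = alpha, var_equal = var_equal)
  direction <- if (cmp$p_value < alpha && fold != 1) {
    if (fold > 1) "up" else "down"
  } else "ns"
  structure(list(gene = gene, fold_change = fold, ddct = ddct,
                 p_value = cmp$p_value, direction = direction,
                 alpha = alpha),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("2^-ddCt relative expression%s\n",
              if (is.na(x$gene)) "" else paste0(" of ", x$gene)))
  cat(sprintf("  ddCt = %.3f  fold change (mutant/WT) = %.3f\n",
              x$ddct, x$fold_change))
  cat(sprintf("  p = %.4g -> %s at alpha = %.2g\n",
              x$p_value, x$direction, x$alpha))
  invisible(x)
}

#' Two-group comparison by Student's t-test
#'
#' Two-sided t-test with a direction call: `"up"` when the second group's
#' mean exceeds the first's at `p < alpha`, `"down"` for the reverse, else
#' `"ns"`. When both groups are constant, equal means give p = 1 and unequal
#' means p = 0 (the t statistic diverges).
#'
#' @param x,y Numeric vectors, >= 2 values each.
#' @param alpha Significance level.
#' @param var_equal Equal-variance (Student) vs Welch.
#' @return List: p_value, direction, mean_x, mean_y.
#' @export
group_compare <- function(x, y, alpha = 0.05, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  if (sd(x) == 0 && sd(y) == 0) {
    p <- if (mean(x) == mean(y)) 1 else 0
  } else {
    p <- t.test(x, y, var.equal = var_equal)$p.value
  }
  direction <- if (p < alpha && mean(y) != mean(x)) {
    if (mean(y) > mean(x)) "up" else "down"
  } else "ns"
  list(p_value = p, direction = direction, mean_x = mean(x), mean_y = mean(y))
}

#' Chlorophyll a and b content from absorbance
#'
#' Spectrophotometric quantification from absorbances at 663 and 645 nm:
#' \deqn{Chl_a = (12.7 A_{663} - 2.69 A_{645}) \times V / (1000 W)}
#' \deqn{Chl_b = (22.9 A_{645} - 4.68 A_{663}) \times V / (1000 W)}
#' with extract volume V (mL) and fresh weight W (g); results in mg per g
#' fresh weight. Pathological absorbance combinations can yield negative
#' values; they are returned as computed, not clamped.
#'
#' @param a663,a645 Absorbances (vectorised).
#' @param v Extract volume in mL (default 1, the standard 1 mL extraction).
#' @param w Sample fresh weight in g; must be > 0.
#' @return data.frame with columns `chl_a`, `chl_b`.
#' @export
#' @examples
#' chlorophyll_content(0.8, 0.4, v = 1, w = 0.03)
chlorophyll_content <- function(a663, a645, v = 1, w) {
  if (any(a663 < 0) || any(a645 < 0)) stop("absorbances must be >= 0")
  if (any(w <= 0)) stop("sample fresh weight W must be > 0")
  data.frame(chl_a = (12.7 * a663 - 2.69 * a645) * v / (1000 * w),
             chl_b = (22.9 * a645 - 4.68 * a663) * v / (1000 * w))
}

#' Chlorophyll-precursor content from absorbance
#'
#' Mg-protoporphyrin IX and protochlorophyllide from absorbances at 575,
#' 590 and 628 nm:
#' \deqn{MgProtoIX = 0.06077 A_{590} - 0.01937 A_{575} - 0.003423 A_{628}}
#' \deqn{Pchld = 0.03563 A_{628} + 0.007225 A_{590} - 0.02955 A_{575}}
#' The linear forms carry no volume/weight normalisation, so the outputs are
#' reported in equation units.
#'
#' @param a575,a590,a628 Absorbances (vectorised).
#' @return data.frame with columns `mg_proto`, `pchld`.
#' @export
#' @examples
#' precursor_content(0.1, 0.2, 0.3)
precursor_content <- function(a575, a590, a628) {
  if (any(c(a575, a590, a628) < 0)) stop("absorbances must be >= 0")
  data.frame(
    mg_proto = 0.06077 * a590 - 0.01937 * a575 - 0.003423 * a628,
    pchld = 0.03563 * a628 + 0.007225 * a590 - 0.02955 * a575)
}
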