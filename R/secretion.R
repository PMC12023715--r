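# Secretion screen: coculture-vs-control log2 fold changes of protein-array
# spot pixel densities with the +/-1 selection threshold.

#' Log2 fold changes of spot densities between two conditions
#'
#' For each analyte, `log2fc = log2((num + pseudocount) /
#' (den + pseudocount))`; an analyte is selected when `|log2fc| >= 1`, the
#' threshold that retains only substantial secretion changes. Duplicate
#' spots per analyte/condition are averaged first (the array-kit
#' convention). Analytes missing either condition are skipped with a
#' warning.
#'
#' @param table data.frame with columns `analyte`, `condition`, `density`
#'   (see [generate_secretion_table()]).
#' @param numerator,denominator condition names (defaults `"coculture"` vs.
#'   `"gb_control"`).
#' @param pseudocount density added to both terms so zero-density spots stay
#'   finite (default 1; set 0 for exact ratios when no zeros occur).
#' @param threshold absolute log2 fold-change selection threshold (default 1).
#' @return data.frame with columns `analyte`, `log2fc`, `selected`,
#'   `direction` (`up_in_coculture` / `down_in_coculture`, named after the
#'   numerator condition when it is the coculture).
#' @export
log2_fold_change <- function(table, numerator = "coculture",
                             denominator = "gb_control", pseudocount = 1,
                             threshold = 1) {
  assert_that(all(c("analyte", "condition", "density") %in% names(table)),
              "table needs columns analyte, condition, density")
  assert_that(all(table$density >= 0), "densities must be nonnegative")
  analytes <- unique(table$analyte)
  rows <- lapply(analytes, function(a) {
    num <- table$density[table$analyte == a & table$condition == numerator]
    den <- table$density[table$analyte == a & table$condition == denominator]
    if (!length(num) || !length(den)) {
      warning("analyte '", a, "' missing a condition; skipped")
      return(NULL)
    }
    fc <- log2((mean(num) + pseudocount) / (mean(den) + pseudocount))
    data.frame(analyte = a, log2fc = fc, selected = abs(fc) >= threshold,
               direction = if (fc >= 0) "up_in_coculture" else "down_in_coculture",
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
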