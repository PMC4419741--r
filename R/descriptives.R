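group_rows <- function(records, group) {
  records$zygosity == group_zygosity(group) & records$sex == group_sex(group)
}

make_group_cor <- function(group, a, b, r, n, level = 0.95) {
  ci <- fisher_ci(r, n, level)
  data.frame(group = group, phenotype_a = a, phenotype_b = b,
             r = r, ci_low = ci[1], ci_high = ci[2], n = n,
             stringsAsFactors = FALSE)
}

#' Phenotypic correlation on a one-twin-per-pair table
#'
#' Pearson correlation between two measures computed on an individual-level
#' table with one randomly selected twin per family (see
#' [select_one_per_pair()]), so rows are independent. Confidence interval by
#' Fisher's z transformation on pairwise-complete rows.
#'
#' @param selected_table output of [select_one_per_pair()]
#' @param pheno_a,pheno_b phenotype names
#' @param level confidence level
#' @return a one-row data frame: group (`"all"`), phenotypes, `r`, CI, `n`
#' @export
phenotypic_correlation <- function(selected_table, pheno_a, pheno_b,
                                   level = 0.95) {
  x <- selected_table[[pheno_a]]
  y <- selected_table[[pheno_b]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("fewer than 3 complete rows for ",
                        pheno_a, " x ", pheno_b)
  r <- stats::cor(x[ok], y[ok])
  make_group_cor("all", pheno_a, pheno_b, r, sum(ok), level)
}

# double-entry correlation of twin-i's a with co-twin's b; with a == b this
# is the cross-twin intraclass correlation
double_entry_cor <- function(records, group, pheno_a, pheno_b, level = 0.95) {
  sel <- records[group_rows(records, group), , drop = FALSE]
  xa1 <- sel[[paste0(pheno_a, "_t1")]]; xa2 <- sel[[paste0(pheno_a, "_t2")]]
  yb1 <- sel[[paste0(pheno_b, "_t1")]]; yb2 <- sel[[paste0(pheno_b, "_t2")]]
  ok <- !is.na(xa1) & !is.na(yb2)
  ok2 <- !is.na(xa2) & !is.na(yb1)
  n_pairs <- sum(ok | ok2)
  if (n_pairs < 3) stop("fewer than 3 complete pairs in group ", group)
  x <- c(xa1[ok], xa2[ok2])
  y <- c(yb2[ok], yb1[ok2])
  r <- stats::cor(x, y)
  # CI uses the number of distinct pairs, not doubled entries
  make_group_cor(group, pheno_a, pheno_b, r, n_pairs, level)
}

#' Cross-twin intraclass correlation
#'
#' Twin resemblance within a zygosity-sex group, estimated as the
#' double-entry Pearson correlation (each pair contributes both twin
#' orderings, making the estimate invariant to the arbitrary labelling of
#' twins). The Fisher-z confidence interval uses the number of pairs, not
#' the doubled entries.
#'
#' @param records twin-pair data frame
#' @param group one of `"MZM"`, `"DZM"`, `"MZF"`, `"DZF"`
#' @param phenotype phenotype name
#' @param level confidence level
#' @return one-row data frame as in [phenotypic_correlation()]
#' @export
cross_twin_icc <- function(records, group, phenotype, level = 0.95) {
  double_entry_cor(records, group, phenotype, phenotype, level)
}

#' Cross-trait cross-twin correlation
#'
#' Correlates one twin's score on one measure with the co-twin's score on
#' another, by double entry (symmetric in twin order). With
#' `pheno_a == pheno_b` this reduces to [cross_twin_icc()]. The comparison of
#' its MZ and DZ values indexes genetic and environmental contributions to
#' the covariance between traits.
#'
#' @inheritParams cross_twin_icc
#' @param pheno_a,pheno_b phenotype names
#' @return one-row data frame as in [phenotypic_correlation()]
#' @export
cross_trait_cross_twin <- function(records, group, pheno_a, pheno_b,
                                   level = 0.95) {
  double_entry_cor(records, group, pheno_a, pheno_b, level)
}

#' Twin correlation table across groups
#'
#' Cross-twin intraclass correlations for every phenotype, and cross-trait
#' cross-twin correlations for every phenotype pair, in each zygosity-sex
#' group.
#'
#' @param records twin-pair data frame
#' @param phenotypes phenotype names (default: all)
#' @param level confidence level
#' @return data frame with one row per group x phenotype (pair)
#' @export
twin_correlation_table <- function(records, phenotypes = twin_phenotypes(records),
                                   level = 0.95) {
  rows <- list()
  for (g in TWIN_GROUPS) {
    for (i in seq_along(phenotypes)) {
      for (j in seq(i, length(phenotypes))) {
        rows[[length(rows) + 1L]] <-
          double_entry_cor(records, g, phenotypes[i], phenotypes[j], level)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
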