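## Group-comparison statistics used for WT-vs-mutant phenotype tables:
## unpaired two-sided Mann-Whitney for pairs of conditions, one-way ANOVA
## for multi-group comparisons.

#' Unpaired two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact enumeration when the combined sample size is at most 20 and
#' there are no ties; tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric samples (non-empty).
#' @param variable optional variable name carried into the result.
#' @return list of class \code{GroupComparison}: \code{statistic} (U),
#'   \code{p_value}, \code{n} (per group), \code{test},
#'   \code{underpowered} (any group below 3 values).
#' @examples
#' mannWhitney(c(1, 2, 3), c(10, 11, 12))$p_value   # exact 0.1
#' @export
mannWhitney <- function(a, b, variable = NA_character_) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) stop("empty sample")
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- (length(a) + length(b) <= 20L) && !ties
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    structure(list(variable = variable,
                   statistic = unname(wt$statistic),
                   p_value = wt$p.value,
                   n = c(length(a), length(b)),
                   test = "Mann-Whitney (unpaired, two-sided)",
                   exact = exact,
                   underpowered = min(length(a), length(b)) < 3L),
              class = "GroupComparison")
}

#' One-way ANOVA across multiple groups
#'
#' Classical equal-variance F test. Fully degenerate inputs (all groups
#' constant) are flagged: F = 0, p = 1 when means agree.
#'
#' @param groups list of numeric samples (>= 2 groups, each >= 2 values).
#' @param variable optional variable name.
#' @return list of class \code{GroupComparison} with \code{statistic}
#'   (F), \code{df}, \code{p_value}, \code{degenerate}.
#' @export
oneWayAnova <- function(groups, variable = NA_character_) {
    groups <- lapply(groups, function(g) g[!is.na(g)])
    if (length(groups) < 2L) stop("need at least 2 groups")
    if (any(vapply(groups, length, integer(1)) < 2L))
        stop("every group needs at least 2 values")
    vals <- unlist(groups)
    fac <- factor(rep(seq_along(groups),
                      vapply(groups, length, integer(1))))
    degenerate <- all(vapply(groups, stats::sd, numeric(1)) == 0)
    if (degenerate) {
        sameMean <- length(unique(vapply(groups, mean, numeric(1)))) == 1L
        return(structure(list(variable = variable,
                              statistic = if (sameMean) 0 else Inf,
                              df = c(length(groups) - 1L,
                                     length(vals) - length(groups)),
                              p_value = if (sameMean) 1 else 0,
                              n = vapply(groups, length, integer(1)),
                              test = "one-way ANOVA", degenerate = TRUE),
                         class = "GroupComparison"))
    }
    ft <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
    structure(list(variable = variable,
                   statistic = unname(ft$statistic),
                   df = unname(ft$parameter),
                   p_value = ft$p.value,
                   n = vapply(groups, length, integer(1)),
                   test = "one-way ANOVA", degenerate = FALSE),
              class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
    cat(x$test, if (!is.na(x$variable)) paste0(" [", x$variable, "]"),
        ": statistic = ", signif(x$statistic, 4),
        ", p = ", signif(x$p_value, 4), " ",
        significanceStars(x$p_value), "\n", sep = "")
    invisible(x)
}

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#'
#' @param p p value(s).
#' @return character vector: \code{"***"}, \code{"**"}, \code{"*"} or
#'   \code{"ns"}.
#' @export
significanceStars <- function(p) {
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", "ns")))
}

#' Wild-type versus mutant comparison table
#'
#' For each requested variable: per-genotype mean and s.e.m. (across
#' cells, pooled over embryos) and a Mann-Whitney test (the default for
#' pairwise condition comparisons) or one-way ANOVA.
#'
#' @param wt,mutant data.frames holding the variables as columns (e.g.
#'   cell tables, anisotropy tables).
#' @param variables character vector of column names to compare.
#' @param test \code{"mann_whitney"} (default) or \code{"anova"}.
#' @param wtConfig,mutantConfig optional parameter echoes; if both are
#'   given they must be identical (measurements must come from one
#'   pipeline configuration).
#' @return data.frame with group means, s.e.m., n, statistic, p value and
#'   stars per variable.
#' @export
genotypeReport <- function(wt, mutant, variables,
                           test = c("mann_whitney", "anova"),
                           wtConfig = NULL, mutantConfig = NULL) {
    test <- match.arg(test)
    if (is.null(wt) || !nrow(wt)) stop("empty wild-type cohort")
    if (is.null(mutant) || !nrow(mutant)) stop("empty mutant cohort")
    if (!is.null(wtConfig) && !is.null(mutantConfig) &&
        !identical(wtConfig, mutantConfig)) {
        d1 <- setdiff(names(wtConfig), names(mutantConfig))
        diffs <- union(d1, names(wtConfig)[vapply(names(wtConfig),
            function(nm) !identical(wtConfig[[nm]], mutantConfig[[nm]]),
            logical(1))])
        stop("config mismatch between genotypes: ",
             paste(diffs, collapse = ", "))
    }
    sem <- function(v) stats::sd(v) / sqrt(length(v))
    rows <- lapply(variables, function(v) {
        if (is.null(wt[[v]]) || is.null(mutant[[v]]))
            stop("variable '", v, "' missing from a cohort")
        x <- wt[[v]][!is.na(wt[[v]])]
        y <- mutant[[v]][!is.na(mutant[[v]])]
        cmp <- if (test == "mann_whitney") mannWhitney(x, y, v)
               else oneWayAnova(list(x, y), v)
        data.frame(variable = v,
                   wt_mean = mean(x), wt_sem = sem(x), wt_n = length(x),
                   mut_mean = mean(y), mut_sem = sem(y), mut_n = length(y),
                   statistic = cmp$statistic, p_value = cmp$p_value,
                   stars = significanceStars(cmp$p_value),
                   test = cmp$test)
    })
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
}
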