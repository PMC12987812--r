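#' Pixel-sampled two-way ANOVA of RSEI
#'
#' Fixed-effects two-way analysis of variance of RSEI samples with group
#' (e.g. resilience-programme membership, or city), year and their
#' interaction, using Type-II sums of squares. Post hoc, Tukey HSD
#' pairwise comparisons are made between all group-by-year cells and
#' summarized within each group across years as a compact-letter
#' display: years sharing a letter are not significantly different at
#' `alpha`.
#'
#' Pixel samples of a raster are spatially autocorrelated, so treating
#' pixels as independent replicates (as is common in this literature)
#' overstates the effective sample size; p-values should be read as
#' descriptive of the sampled scenes.
#'
#' @param samples Data frame with columns `rsei` (numeric), `group` and
#'   `year` (coercible to factors); every group-by-year cell needs at
#'   least 2 observations.
#' @param alpha Significance level for the post hoc letters (default 0.05).
#' @return An `rsei_anova` object: `effects` (term, df, sumsq, statistic,
#'   p.value), `cell_means` (group, year, mean, sd, n), `tukey`
#'   (within-group pairwise comparisons) and `letters` (group, year,
#'   letters).
#' @export
two_way_anova <- function(samples, alpha = 0.05) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("rsei", "group", "year") %in% names(samples)))
  samples$group <- factor(samples$group)
  samples$year <- factor(samples$year)
  if (nlevels(samples$group) < 2L || nlevels(samples$year) < 2L) {
    stop("design error: need at least 2 groups and 2 years", call. = FALSE)
  }
  cell_n <- table(samples$group, samples$year)
  if (any(cell_n < 2L)) {
    stop("design error: every group x year cell needs >= 2 observations",
         call. = FALSE)
  }
  mod <- stats::aov(rsei ~ group * year, data = samples)
  a2 <- car::Anova(mod, type = 2)
  eff <- tibble::tibble(
    term = trimws(rownames(a2)),
    sumsq = a2[["Sum Sq"]],
    df = a2[["Df"]],
    statistic = a2[["F value"]],
    p.value = a2[["Pr(>F)"]]
  )
  cell_means <- samples |>
    dplyr::group_by(.data$group, .data$year) |>
    dplyr::summarise(mean = mean(.data$rsei), sd = stats::sd(.data$rsei),
                     n = dplyr::n(), .groups = "drop")

  # Tukey HSD over the cell-means parameterization, with safe cell codes
  # so labels containing '-' or ':' cannot break pair parsing.
  glev <- levels(samples$group); ylev <- levels(samples$year)
  code <- function(g, y) paste0("G", match(g, glev), "_Y", match(y, ylev))
  samples$cell <- factor(code(samples$group, samples$year))
  tk <- stats::TukeyHSD(stats::aov(rsei ~ cell, data = samples))$cell
  pair <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  decode <- function(s) {
    m <- regmatches(s, regexec("^G(\\d+)_Y(\\d+)$", s))
    t(vapply(m, function(x) c(glev[as.integer(x[2])], ylev[as.integer(x[3])]),
             character(2)))
  }
  p1 <- decode(pair[, 1]); p2 <- decode(pair[, 2])
  tukey <- tibble::tibble(
    group1 = p1[, 1], year1 = p1[, 2],
    group2 = p2[, 1], year2 = p2[, 2],
    diff = unname(tk[, "diff"]), lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]), p.adj = unname(tk[, "p adj"])
  )

  letters_tbl <- purrr::map_dfr(glev, function(g) {
    within_g <- tukey |>
      dplyr::filter(.data$group1 == g, .data$group2 == g)
    sig <- matrix(FALSE, length(ylev), length(ylev),
                  dimnames = list(ylev, ylev))
    for (r in seq_len(nrow(within_g))) {
      if (within_g$p.adj[r] < alpha) {
        sig[within_g$year1[r], within_g$year2[r]] <- TRUE
        sig[within_g$year2[r], within_g$year1[r]] <- TRUE
      }
    }
    tibble::tibble(group = g, year = ylev,
                   letters = compact_letters(ylev, sig))
  })

  structure(list(effects = eff, cell_means = cell_means, tukey = tukey,
                 letters = letters_tbl, alpha = alpha),
            class = "rsei_anova")
}

#' Compact-letter display from a significance matrix
#'
#' Insert-and-absorb letter assignment: starting from one set holding all
#' levels, every significantly different pair splits each set containing
#' both, and sets that become subsets of others are absorbed. Levels
#' share a letter if and only if they are not significantly different.
#'
#' @param levels Character vector of level names.
#' @param sig Logical matrix (levels x levels); `TRUE` = significantly
#'   different.
#' @return Character vector of letter strings, one per level.
#' @export
compact_letters <- function(levels, sig) {
  sets <- list(levels)
  k <- length(levels)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      a <- levels[i]; b <- levels[j]
      new_sets <- list()
      for (s in sets) {
        if (a %in% s && b %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      new_sets <- Filter(function(s) length(s) > 0, new_sets)
      # absorb: dedupe, then drop sets strictly contained in another
      new_sets <- unique(lapply(new_sets, sort))
      keep <- rep(TRUE, length(new_sets))
      for (p in seq_along(new_sets)) {
        for (q in seq_along(new_sets)) {
          if (p != q && keep[q] && all(new_sets[[p]] %in% new_sets[[q]])) {
            keep[p] <- FALSE
            break
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  ord <- order(vapply(sets, function(s) min(match(s, levels)), numeric(1)))
  sets <- sets[ord]
  out <- vapply(levels, function(lv) {
    paste(letters[which(vapply(sets, function(s) lv %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  unname(out)
}

#' @export
print.rsei_anova <- function(x, ...) {
  cat("Two-way ANOVA (Type II):\n")
  print(as.data.frame(x$effects), digits = 4)
  cat("\nCompact letters (alpha =", x$alpha, "):\n")
  print(tidyr::pivot_wider(x$letters, names_from = "year",
                           values_from = "letters"))
  invisible(x)
}

#' Tidy / glance methods for `rsei_anova`
#'
#' @param x An `rsei_anova`.
#' @param ... Unused.
#' @return `tidy()`: the effects table. `glance()`: one row with the
#'   group, year and interaction p-values.
#' @export
#' @exportS3Method generics::tidy
tidy.rsei_anova <- function(x, ...) x$effects

#' @rdname tidy.rsei_anova
#' @export
#' @exportS3Method generics::glance
glance.rsei_anova <- function(x, ...) {
  p <- stats::setNames(x$effects$p.value, x$effects$term)
  tibble::tibble(
    p_group = unname(p["group"]),
    p_year = unname(p["year"]),
    p_interaction = unname(p["group:year"])
  )
}

#' Seeded pixel sample from a raster
#'
#' Draws a uniform random sample of valid pixel values, the sampling unit
#' used by the pixel-based ANOVA.
#'
#' @param raster Raster-like object.
#' @param n Sample size (default 2000); capped at the number of valid
#'   pixels.
#' @param seed Seed.
#' @return Numeric vector of sampled values.
#' @export
sample_pixels <- function(raster, n = 2000L, seed = 20160101L) {
  v <- as_raster_matrix(raster)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no valid pixels to sample", call. = FALSE)
  n <- min(n, length(v))
  withr::with_seed(seed, sample(v, n))
}
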