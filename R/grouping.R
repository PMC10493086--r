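#' Group cultivars with overlapping cultivation periods
#'
#' In `config` mode, reproduces a stated group membership (per-season groups
#' with fixed periods) after validating that every member is a known
#' cultivar whose cultivation span intersects the group period. In
#' `overlap` mode, returns the connected components of the interval-overlap
#' graph of the cultivation spans within each season, with the component
#' period being the union range of its members' spans.
#'
#' @param spans Cultivation spans: a tibble with columns `cultivar`,
#'   `season`, `first_year`, `last_year` (several rows per cultivar
#'   allowed), e.g. [taichung_cultivars()].
#' @param mode `"config"` or `"overlap"`.
#' @param groups For `config` mode: a membership tibble with columns
#'   `season`, `group`, `start_year`, `end_year`, `cultivar`, `excluded`;
#'   default [taichung_groups()].
#' @return A tibble with one row per group-member: `season`, `group`,
#'   `start_year`, `end_year`, `cultivar`, `excluded`.
#' @export
#' @examples
#' build_groups(taichung_cultivars())
build_groups <- function(spans, mode = c("config", "overlap"),
                         groups = taichung_groups()) {
  mode <- match.arg(mode)
  spans <- as_tibble(spans)
  check_columns(spans, c("cultivar", "season", "first_year", "last_year"),
                "`spans`")
  if (nrow(spans) == 0L) {
    stop_ricedelta("`spans` is empty.", "config")
  }
  if (mode == "config") {
    groups <- as_tibble(groups)
    check_columns(groups, c("season", "group", "start_year", "end_year",
                            "cultivar", "excluded"), "`groups`")
    for (i in seq_len(nrow(groups))) {
      m <- groups[i, ]
      sp <- spans[spans$cultivar == m$cultivar & spans$season == m$season, ]
      if (nrow(sp) == 0L) {
        stop_ricedelta(
          sprintf("Group '%s' (%s) names unknown cultivar '%s'.",
                  m$group, m$season, m$cultivar),
          "config"
        )
      }
      intersects <- any(sp$first_year <= m$end_year &
                          sp$last_year >= m$start_year)
      if (!intersects) {
        stop_ricedelta(
          sprintf(
            "Cultivar '%s' has no cultivation span inside group '%s' (%s, %d-%d).",
            m$cultivar, m$group, m$season, m$start_year, m$end_year
          ),
          "config"
        )
      }
    }
    return(arrange(groups, .data$season, .data$start_year, .data$group))
  }

  # overlap mode: connected components via union-find on spans
  purrr::map(unique(spans$season), function(s) {
    sub <- spans[spans$season == s, ]
    ids <- unique(sub$cultivar)
    parent <- setNames(seq_along(ids), ids)
    find <- function(i) {
      while (parent[[i]] != i) i <- parent[[i]]
      i
    }
    overlap <- function(a, b) {
      any(outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
        a$first_year[i] <= b$last_year[j] & a$last_year[i] >= b$first_year[j]
      }))
    }
    for (i in seq_along(ids)) {
      for (j in seq_len(i - 1L)) {
        if (overlap(sub[sub$cultivar == ids[i], ],
                    sub[sub$cultivar == ids[j], ])) {
          parent[[find(i)]] <- find(j)
        }
      }
    }
    comp <- vapply(seq_along(ids), find, integer(1))
    purrr::map(unique(comp), function(cid) {
      members <- ids[comp == cid]
      msp <- sub[sub$cultivar %in% members, ]
      tibble(
        season = s,
        group = sprintf("%d-%d", min(msp$first_year), max(msp$last_year)),
        start_year = min(msp$first_year), end_year = max(msp$last_year),
        cultivar = members, excluded = FALSE
      )
    }) |> bind_rows()
  }) |>
    bind_rows() |>
    arrange(.data$season, .data$start_year, .data$group)
}

#' Summarize percent coefficients over a group of cultivars
#'
#' The per-variable arithmetic mean and sample (n - 1) standard deviation of
#' the members' percent coefficients. A single-member group has no sample
#' SD; it is reported as `NA`.
#'
#' @param members A tibble with one row per member carrying columns `pct_T`,
#'   `pct_DTR`, `pct_R`, `pct_S` (e.g. rows of [regress_cultivars()] output
#'   or of [taichung_coefficients()]).
#' @return A tibble with columns `variable`, `mean_pct`, `sd_pct`,
#'   `n_members`.
#' @export
#' @examples
#' coefs <- dplyr::filter(taichung_coefficients(), season == "cool",
#'                        cultivar %in% c("NM", "TCS2", "BK", "TCS6"))
#' summarize_group(coefs)
summarize_group <- function(members) {
  members <- as_tibble(members)
  pct_cols <- paste0("pct_", climate_vars)
  check_columns(members, pct_cols, "`members`")
  if (nrow(members) == 0L) {
    stop_ricedelta("`members` must contain at least one cultivar.", "argument")
  }
  tibble(
    variable = climate_vars,
    mean_pct = unname(vapply(pct_cols, function(cl) mean(members[[cl]]),
                             numeric(1))),
    sd_pct = if (nrow(members) < 2L) NA_real_ else
      unname(vapply(pct_cols, function(cl) sd(members[[cl]]), numeric(1))),
    n_members = nrow(members)
  )
}

#' Group summaries for every configured group
#'
#' @param results Cultivar-level results carrying `season`, `cultivar` and
#'   the `pct_*` columns.
#' @param groups Group membership tibble as from [build_groups()].
#' @return A tibble with one row per group-variable: `season`, `group`,
#'   `start_year`, `end_year`, `variable`, `mean_pct`, `sd_pct`,
#'   `n_members`, `excluded`.
#' @export
group_summaries <- function(results, groups = taichung_groups()) {
  results <- as_tibble(results)
  check_columns(results, c("season", "cultivar", paste0("pct_", climate_vars)),
                "`results`")
  groups <- as_tibble(groups)
  keys <- dplyr::distinct(groups, .data$season, .data$group,
                          .data$start_year, .data$end_year, .data$excluded)
  purrr::pmap(keys, function(season, group, start_year, end_year, excluded) {
    members_ids <- groups$cultivar[groups$season == season &
                                     groups$group == group]
    members <- results[results$season == season &
                         results$cultivar %in% members_ids, ]
    if (nrow(members) == 0L) {
      return(NULL)
    }
    summarize_group(members) |>
      mutate(season = season, group = group,
             start_year = start_year, end_year = end_year,
             excluded = excluded) |>
      select("season", "group", "start_year", "end_year", "variable",
             "mean_pct", "sd_pct", "n_members", "excluded")
  }) |>
    bind_rows() |>
    arrange(.data$season, .data$start_year, .data$group)
}

# Pairwise Pearson correlation object over the columns of `data`.
new_cor_matrix <- function(data, labels, season = NA_character_) {
  k <- length(labels)
  r <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  p <- r
  nmat <- matrix(NA_integer_, k, k, dimnames = list(labels, labels))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k)) {
    nmat[i, i] <- sum(!is.na(data[[labels[i]]]))
    for (j in seq_len(k)) {
      if (j >= i) next
      ok <- stats::complete.cases(data[[labels[i]]], data[[labels[j]]])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) < 3L) next   # pair flagged undefined
      ct <- cor.test(data[[labels[i]]][ok], data[[labels[j]]][ok],
                     method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  marker <- matrix(significance_marker(as.vector(p)), k, k,
                   dimnames = list(labels, labels))
  structure(
    list(labels = labels, r = r, n = nmat, p = p, marker = marker,
         season = season),
    class = "cor_matrix"
  )
}

#' @export
print.cor_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<cor_matrix%s>\n",
              if (!is.na(x$season)) paste0(": ", x$season, " season") else ""))
  shown <- matrix(paste0(format(round(x$r, digits)), x$marker),
                  nrow(x$r), dimnames = dimnames(x$r))
  shown[is.na(x$r)] <- "NA"
  print(shown, quote = FALSE)
  invisible(x)
}

#' Correlations between climate first differences
#'
#' Pairwise Pearson correlations of the first differences of the seasonal
#' climate variables (`dT`, `dDTR`, `dR`, `dS`) within one season, on
#' pairwise-complete pairs, with significance markers from
#' [significance_marker()]. Pairs with fewer than 3 complete observations
#' are left undefined (`NA`).
#'
#' @param climate Seasonal climate tibble.
#' @param season Season name to analyse.
#' @return A `cor_matrix` object; use [tidy()] for the long form.
#' @export
climate_delta_correlations <- function(climate, season) {
  cdiff <- climate_first_differences(climate)
  cdiff <- cdiff[cdiff$season == season, ]
  if (nrow(cdiff) == 0L) {
    stop_ricedelta(sprintf("No climate rows for season '%s'.", season),
                   "argument")
  }
  new_cor_matrix(cdiff, paste0("d", climate_vars), season = season)
}

#' Correlations between the yields of cultivar pairs within groups
#'
#' For each group, Pearson correlations between member pairs over their
#' overlapping trial years, on yield first differences by default (the same
#' detrended scale as the regression) or on yield levels with
#' `use = "level"`. Pairs sharing fewer than 3 overlapping observations are
#' omitted (with a log entry in the `omitted` attribute).
#'
#' @param yields Yield tibble (`cultivar`, `season`, `year`, `yield`).
#' @param groups Group membership tibble as from [build_groups()].
#' @param use `"diff"` (default) or `"level"`.
#' @return A long tibble: `season`, `group`, `cultivar_a`, `cultivar_b`,
#'   `r`, `n`, `marker`.
#' @export
pairwise_yield_correlations <- function(yields, groups = taichung_groups(),
                                        use = c("diff", "level")) {
  use <- match.arg(use)
  yields <- as_tibble(yields)
  check_columns(yields, c("cultivar", "season", "year", "yield"), "`yields`")
  series_of <- function(cultivar, season) {
    sub <- yields[yields$cultivar == cultivar & yields$season == season, ]
    s <- tibble(year = sub$year, value = sub$yield)
    if (use == "diff") {
      fd <- first_difference(s)
      tibble(year = fd$year, value = fd$delta)
    } else {
      s
    }
  }
  keys <- dplyr::distinct(groups, .data$season, .data$group)
  omitted <- character()
  rows <- purrr::pmap(keys, function(season, group) {
    members <- groups$cultivar[groups$season == season &
                                 groups$group == group]
    if (length(members) < 2L) return(NULL)
    pairs <- utils::combn(sort(members), 2, simplify = FALSE)
    purrr::map(pairs, function(pr) {
      a <- series_of(pr[1], season)
      b <- series_of(pr[2], season)
      shared <- intersect(a$year, b$year)
      if (length(shared) < 3L) {
        omitted <<- c(omitted,
                      sprintf("%s-%s (%s %s): %d shared observations",
                              pr[1], pr[2], season, group, length(shared)))
        return(NULL)
      }
      ct <- cor.test(a$value[match(shared, a$year)],
                     b$value[match(shared, b$year)], method = "pearson")
      tibble(
        season = season, group = group,
        cultivar_a = pr[1], cultivar_b = pr[2],
        r = unname(ct$estimate), n = length(shared),
        marker = significance_marker(ct$p.value)
      )
    }) |> bind_rows()
  })
  out <- bind_rows(rows)
  attr(out, "omitted") <- omitted
  out
}
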