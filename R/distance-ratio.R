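#' Within- versus between-environment relative distance ratios
#'
#' Quantifies how tightly a set of focal sites (e.g. the oral body sites)
#' cluster against the background of all other sites. For each sample `s`
#' belonging to a focal site `f`, distances are taken from `s` to all
#' samples in every site except `f` itself; those distances are split into
#' the other focal sites (numerator) and the non-focal sites (denominator),
#' and the ratio of the two means is reported. The distribution of these
#' per-sample ratios is the statistic: the lower the ratios, the more
#' similar the focal-site communities are to each other relative to the
#' background.
#'
#' @param d A `dist`/`ogu_dist`.
#' @param sites Site labels per sample: a named vector, a vector along the
#'   samples of `d`, or a tibble with `sample_id` and a site column.
#' @param focal_sites Character vector of at least 2 focal site names.
#' @return A tibble with one row per focal sample: `sample_id`, `site`,
#'   `mean_within` (mean distance to the other focal sites),
#'   `mean_between` (mean distance to non-focal sites), `ratio`.
#' @export
relative_distance_ratio <- function(d, sites, focal_sites) {
  m <- as.matrix(d)
  sites <- align_groups(sites, rownames(m))
  names(sites) <- rownames(m)
  focal_sites <- unique(as.character(focal_sites))
  if (length(focal_sites) < 2) abort("need at least 2 focal sites")
  missing <- setdiff(focal_sites, sites)
  if (length(missing) > 0) {
    abort(paste0("focal site(s) absent from metadata: ",
                 paste(missing, collapse = ", ")))
  }
  focal_samples <- names(sites)[sites %in% focal_sites]
  rows <- lapply(focal_samples, function(s) {
    f <- sites[[s]]
    within_ids <- names(sites)[sites %in% setdiff(focal_sites, f)]
    between_ids <- names(sites)[!sites %in% focal_sites]
    if (length(within_ids) == 0) {
      abort(paste0("sample ", s, " has no counterpart in the other focal sites"))
    }
    if (length(between_ids) == 0) {
      abort(paste0("sample ", s, " has no non-focal counterpart"))
    }
    mw <- mean(m[s, within_ids])
    mb <- mean(m[s, between_ids])
    tibble(sample_id = s, site = f, mean_within = mw, mean_between = mb,
           ratio = mw / mb)
  })
  bind_rows(rows)
}
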