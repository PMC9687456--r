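# Relative qPCR quantification by the 2^-ddCt method with a reference
# gene and a calibrator group, plus Welch testing of replicate delta-Ct.

#' Relative quantity by the 2^-ddCt method
#'
#' `dCt = ct_target - ct_reference`, `ddCt = dCt - calibrator_delta_ct`,
#' `RQ = 2^-ddCt`. Vectorised; all inputs must be finite.
#'
#' @param ct_target target-gene Ct values.
#' @param ct_reference reference-gene (housekeeping, beta-actin role) Ct
#'   values.
#' @param calibrator_delta_ct calibrator dCt (e.g. the control group's
#'   mean dCt); 0 gives the unscaled 2^-dCt.
#' @return relative quantities (> 0).
#' @export
#' @examples
#' relative_quantity(20, 15, 5)  # ddCt = 0 -> 1
#' relative_quantity(21, 15, 5)  # ddCt = 1 -> 0.5
relative_quantity <- function(ct_target, ct_reference, calibrator_delta_ct = 0) {
  vals <- c(ct_target, ct_reference, calibrator_delta_ct)
  if (any(!is.finite(vals))) {
    abort("relative_quantity() requires finite Ct inputs")
  }
  2^-((ct_target - ct_reference) - calibrator_delta_ct)
}

#' Compare qPCR expression between two groups
#'
#' Per gene: dCt per replicate, calibrator = mean dCt of the reference
#' group, mean RQ per group (2^-ddCt of the group mean dCt), Welch
#' two-sample t-test on the replicate dCt values, and a direction label
#' for the non-reference group (lower dCt = higher expression = `up`).
#'
#' @param measurements tibble with columns `sample`, `group`, `gene`,
#'   `ct_target`, `ct_reference` (one row per replicate).
#' @param reference_group calibrator group (default `"fine"`).
#' @param alpha significance threshold for the `significant` flag.
#' @return tibble: `gene`, `n_ref`, `n_other`, `mean_rq_ref`,
#'   `mean_rq_other`, `p_value`, `direction`, `significant`.
#' @export
qpcr_compare <- function(measurements, reference_group = "fine",
                         alpha = 0.05) {
  check_columns(measurements, c("group", "gene", "ct_target", "ct_reference"),
                "measurements")
  if (any(!is.finite(measurements$ct_target)) ||
      any(!is.finite(measurements$ct_reference)) ||
      any(measurements$ct_target <= 0) ||
      any(measurements$ct_reference <= 0)) {
    abort("Ct values must be positive and finite")
  }
  groups <- unique(measurements$group)
  if (!(reference_group %in% groups) || length(groups) != 2L) {
    abort("`measurements` must contain exactly two groups including the reference group")
  }
  other_group <- setdiff(groups, reference_group)
  m <- measurements %>% mutate(dct = .data$ct_target - .data$ct_reference)

  purrr::map_dfr(unique(m$gene), function(g) {
    sub <- m %>% filter(.data$gene == g)
    ref <- sub$dct[sub$group == reference_group]
    oth <- sub$dct[sub$group == other_group]
    if (length(ref) < 2L || length(oth) < 2L) {
      abort(sprintf("gene %s needs >= 2 replicates per group", g))
    }
    cal <- mean(ref)
    tt <- t.test(oth, ref) # Welch by default
    tibble(gene = g, n_ref = length(ref), n_other = length(oth),
           mean_rq_ref = relative_quantity(mean(ref), 0, cal),
           mean_rq_other = relative_quantity(mean(oth), 0, cal),
           p_value = tt$p.value,
           direction = if_else(mean(oth) < mean(ref), "up", "down"),
           significant = tt$p.value < alpha)
  })
}

#' Simulate a qPCR Ct table with known group shifts
#'
#' Generates replicate Ct values for a target and a reference gene in two
#' groups; `shift` is the planted dCt difference (reference-group dCt
#' minus the other group's dCt), so positive shifts mean the non-reference
#' group is up-expressed by `2^shift`-fold.
#'
#' @param genes character vector of gene names.
#' @param shift planted dCt shift per gene (recycled).
#' @param n_replicates replicates per group (default 6).
#' @param sd replicate standard deviation in cycles (default 0.2).
#' @param groups group labels, non-reference first.
#' @param reference_group name of the calibrator group.
#' @param seed integer seed.
#' @return measurement tibble suitable for [qpcr_compare()].
#' @export
simulate_qpcr <- function(genes, shift, n_replicates = 6L, sd = 0.2,
                          groups = c("coarse", "fine"),
                          reference_group = "fine", seed = 1L) {
  shift <- rep_len(shift, length(genes))
  withr::with_seed(seed, {
    purrr::map_dfr(seq_along(genes), function(i) {
      base_dct <- runif(1, 3, 8)
      purrr::map_dfr(groups, function(grp) {
        dct <- if (grp == reference_group) base_dct else base_dct - shift[i]
        ref_ct <- rnorm(n_replicates, 15, sd)
        tibble(sample = sprintf("%s_%d", grp, seq_len(n_replicates)),
               group = grp, gene = genes[i],
               ct_target = ref_ct + dct + rnorm(n_replicates, 0, sd),
               ct_reference = ref_ct)
      })
    })
  })
}
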