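#' Planted-architecture recovery benchmark
#'
#' Runs the full annotation pipeline on freshly generated synthetic entries
#' (default: [default_synthetic_spec()] — three domains, one assembly, one
#' split domain) across a series of seeds and scores recovery of the planted
#' truth: boundary agreement via [compare_architecture()], split-domain
#' sensitivity and false-split rate, and contact-call accuracy over all
#' domain pairs (a pair counts as correct when both members are matched to
#' planted domains and the contact flag equals the planted rigidity
#' relation).
#'
#' @param n_seeds Number of independent entries (default 50).
#' @param base_seed First seed; entries use `base_seed + 0 ... n_seeds - 1`.
#' @param spec_fun Function mapping a seed to a [synthetic_spec()].
#' @param config An [annotate_config()].
#' @param slack Boundary slack in residues (default 5).
#' @return List with `boundary_agreement`, `split_sensitivity`,
#'   `false_split_rate`, `contact_accuracy` (all in [0, 1]), `n_seeds`, and a
#'   per-seed data frame `per_seed`.
#' @export
recovery_benchmark <- function(n_seeds = 50L, base_seed = 0L,
                               spec_fun = default_synthetic_spec,
                               config = annotate_config(), slack = 5L) {
  rows <- vector("list", n_seeds)
  for (k in seq_len(n_seeds)) {
    sp <- spec_fun(base_seed + k - 1L)
    gen <- generate_model(sp)
    pae <- generate_pae(sp)
    arch <- annotate(gen$model, pae, config)
    truth <- gen$truth
    cmp <- compare_architecture(arch, truth$architecture, slack = slack)
    # map planted domain ids to called domain ids
    map <- stats::setNames(cmp$matches$matched_id, cmp$matches$ref_id)
    called_split <- stats::setNames(
      vapply(arch$domains, `[[`, logical(1), "split"),
      vapply(arch$domains, `[[`, character(1), "domain_id"))
    truth_split <- vapply(truth$architecture$domains, `[[`, logical(1), "split")
    names(truth_split) <- vapply(truth$architecture$domains, `[[`,
                                 character(1), "domain_id")
    split_found <- vapply(names(truth_split)[truth_split], function(d)
      !is.na(map[d]) && isTRUE(called_split[map[d]]), logical(1))
    false_split <- vapply(names(truth_split)[!truth_split], function(d)
      !is.na(map[d]) && isTRUE(called_split[map[d]]), logical(1))
    # contact accuracy over all unordered pairs of planted domains
    ids <- names(truth_split)
    pair_ok <- logical(0)
    if (length(ids) >= 2L) {
      cmb <- utils::combn(sort(ids), 2)
      truth_ct <- paste(truth$contact_pairs$domain_a,
                        truth$contact_pairs$domain_b)
      called_ct <- arch$contacts
      pair_ok <- vapply(seq_len(ncol(cmb)), function(j) {
        a <- cmb[1, j]; b <- cmb[2, j]
        want <- paste(a, b) %in% truth_ct
        ca <- map[a]; cb <- map[b]
        if (is.na(ca) || is.na(cb)) return(FALSE)
        hit <- (called_ct$domain_a == ca & called_ct$domain_b == cb) |
          (called_ct$domain_a == cb & called_ct$domain_b == ca)
        if (!any(hit)) return(!want)
        called_ct$is_contact[which(hit)[1]] == want
      }, logical(1))
    }
    rows[[k]] <- data.frame(seed = base_seed + k - 1L,
                            agreement = cmp$agreement,
                            n_split_truth = sum(truth_split),
                            n_split_found = sum(split_found),
                            n_false_split = sum(false_split),
                            n_nonsplit_truth = sum(!truth_split),
                            n_pairs = length(pair_ok),
                            n_pairs_ok = sum(pair_ok))
  }
  per <- do.call(rbind, rows)
  list(boundary_agreement = mean(per$agreement),
       split_sensitivity = sum(per$n_split_found) / sum(per$n_split_truth),
       false_split_rate = sum(per$n_false_split) / sum(per$n_nonsplit_truth),
       contact_accuracy = sum(per$n_pairs_ok) / sum(per$n_pairs),
       n_seeds = n_seeds,
       per_seed = per)
}

#' Two-state mobility classification of the PARP1-shaped scenario
#'
#' Generates the [parp1_like_spec()] intensity profiles for the free state
#' (nothing immobilized) and the DNA-bound state (everything but BRCT
#' incorporated into the rigid particle) and classifies per-domain mobility
#' against the planted architecture.
#'
#' @param seed Integer seed.
#' @param hi,lo Classification thresholds, see [domain_mobility()].
#' @return List with character vectors `free` and `bound` (class per domain,
#'   named by domain id).
#' @export
mobility_scenario <- function(seed = 0L, hi = 0.5, lo = 0.2) {
  sp <- parp1_like_spec(seed)
  truth <- ground_truth(sp)
  immob <- attr(sp, "immobilized_in_bound")
  classes <- function(immobilized) {
    tab <- generate_intensity_profiles(sp, immobilized)
    per <- domain_mobility(tab, truth$architecture, hi = hi, lo = lo)$per_domain
    stats::setNames(per$class, per$domain_id)
  }
  list(free = classes(character()), bound = classes(immob))
}
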