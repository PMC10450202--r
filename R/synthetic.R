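#' Specification for a synthetic AlphaFold-style entry
#'
#' Describes a chain as an ordered list of structured domains and disordered
#' linkers, which domains form mutually rigid assemblies, and the noise
#' levels of the emulated outputs. A domain id that occurs in more than one
#' (non-adjacent) element is a planted split domain: one spatial unit whose
#' sequence is interrupted by the intervening elements. The generators
#' [generate_model()], [generate_pae()] and [generate_intensity_profiles()]
#' all draw from a generator seeded with `seed`, so identical spec + seed
#' give bit-identical outputs.
#'
#' @param elements List of elements, each a list with `kind` (`"domain"` or
#'   `"linker"`), `length` (residues) and, for domains, `domain_id`.
#' @param assemblies List of character vectors; the domain ids inside one
#'   vector are declared mutually rigid (low interdomain PAE). Domains not
#'   mentioned are mobile relative to everything else.
#' @param noise List with `plddt_sigma`, `pae_sigma`, `intensity_sigma`.
#' @param seed Integer seed (required for reproducibility; default 0).
#' @param entry_id Identifier given to generated outputs.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(elements,
                           assemblies = list(),
                           noise = list(plddt_sigma = 3, pae_sigma = 0.5,
                                        intensity_sigma = 0.1),
                           seed = 0L,
                           entry_id = "synthetic") {
  if (!length(elements)) stop("spec needs at least one element")
  elements <- lapply(elements, function(e) {
    if (!e$kind %in% c("domain", "linker")) stop("element kind must be domain or linker")
    if (!is.numeric(e$length) || e$length < 1) stop("element length must be >= 1")
    if (e$kind == "domain" && is.null(e$domain_id))
      stop("domain elements need a domain_id")
    if (e$kind == "linker" && !is.null(e$domain_id))
      stop("linkers never carry a domain_id")
    list(kind = e$kind, length = as.integer(e$length),
         domain_id = if (e$kind == "domain") as.character(e$domain_id) else NULL)
  })
  total <- sum(vapply(elements, `[[`, integer(1), "length"))
  if (total < 30L) stop("total chain length must be >= 30 residues")
  dom_ids <- unique(unlist(lapply(elements, `[[`, "domain_id")))
  for (a in assemblies) {
    if (!all(a %in% dom_ids))
      stop("assembly references unknown domain id(s): ",
           paste(setdiff(a, dom_ids), collapse = ", "))
    if (length(a) < 2L) stop("an assembly must contain >= 2 domains")
  }
  if (length(unlist(assemblies)) != length(unique(unlist(assemblies))))
    stop("a domain may belong to at most one assembly")
  for (nm in c("plddt_sigma", "pae_sigma", "intensity_sigma"))
    if (!is.numeric(noise[[nm]]) || noise[[nm]] < 0)
      stop("noise$", nm, " must be a non-negative number")
  occ <- lapply(dom_ids, function(d)
    which(vapply(elements, function(e) identical(e$domain_id, d), logical(1))))
  names(occ) <- dom_ids
  structure(list(elements = elements,
                 assemblies = assemblies,
                 split_memberships = occ[lengths(occ) > 1L],
                 noise = noise,
                 seed = as.integer(seed),
                 entry_id = entry_id,
                 length = total),
            class = "synthetic_spec")
}

# Per-element start/end positions and per-residue annotation.
#' @noRd
spec_layout <- function(spec) {
  len <- vapply(spec$elements, `[[`, integer(1), "length")
  end <- cumsum(len)
  start <- end - len + 1L
  dom <- rep(NA_character_, spec$length)
  for (i in seq_along(spec$elements)) {
    d <- spec$elements[[i]]$domain_id
    if (!is.null(d)) dom[start[i]:end[i]] <- d
  }
  list(start = start, end = end, domain = dom,
       kind = vapply(spec$elements, `[[`, character(1), "kind"))
}

#' Default synthetic study conditions
#'
#' Three structured domains on disordered linkers: a split domain `A`
#' (70 + 50 residues, interrupted by a 165-residue insertion that carries
#' domain `B`), domain `B` (110 residues) rigidly packed against `A` (one
#' declared assembly), and an independently mobile domain `C` (90 residues);
#' 400 residues in total. This emulates the recurring motif of the PARP
#' family models: a rigid two-domain arrangement containing a split domain,
#' plus a flexible singleton.
#'
#' @param seed Integer seed.
#' @return A [synthetic_spec()].
#' @export
default_synthetic_spec <- function(seed = 0L) {
  synthetic_spec(
    elements = list(
      list(kind = "domain", length = 70, domain_id = "A"),
      list(kind = "linker", length = 25),
      list(kind = "domain", length = 110, domain_id = "B"),
      list(kind = "linker", length = 30),
      list(kind = "domain", length = 50, domain_id = "A"),
      list(kind = "linker", length = 25),
      list(kind = "domain", length = 90, domain_id = "C")),
    assemblies = list(c("A", "B")),
    seed = seed,
    entry_id = sprintf("synthetic-default-%d", seed))
}

#' PARP1-shaped synthetic scenario
#'
#' Six domains (three N-terminal zinc fingers, BRCT, WGR and a large
#' catalytic domain) connected by linkers, mimicking the 1014-residue PARP1
#' layout. In the DNA-bound state everything except BRCT collapses into one
#' rigid particle ("beads on a string that collapse"), which is expressed
#' here as the declared assembly and as the default `immobilized` set for
#' [generate_intensity_profiles()].
#'
#' @param seed Integer seed.
#' @return A [synthetic_spec()]. The attribute `"immobilized_in_bound"`
#'   holds the domain ids incorporated into the bound rigid body.
#' @export
parp1_like_spec <- function(seed = 0L) {
  sp <- synthetic_spec(
    elements = list(
      list(kind = "domain", length = 90, domain_id = "ZnF1"),
      list(kind = "linker", length = 15),
      list(kind = "domain", length = 95, domain_id = "ZnF2"),
      list(kind = "linker", length = 25),
      list(kind = "domain", length = 110, domain_id = "ZnF3"),
      list(kind = "linker", length = 40),
      list(kind = "domain", length = 115, domain_id = "BRCT"),
      list(kind = "linker", length = 45),
      list(kind = "domain", length = 95, domain_id = "WGR"),
      list(kind = "linker", length = 15),
      list(kind = "domain", length = 360, domain_id = "CAT")),
    assemblies = list(c("ZnF1", "ZnF2", "ZnF3", "WGR", "CAT")),
    seed = seed,
    entry_id = sprintf("synthetic-parp1-%d", seed))
  attr(sp, "immobilized_in_bound") <- c("ZnF1", "ZnF2", "ZnF3", "WGR", "CAT")
  sp
}

#' Planted ground truth for a synthetic spec
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `architecture` (the planted [architecture()]),
#'   `contact_pairs` (data frame of domain-id pairs declared mutually rigid)
#'   and `domain_ids`.
#' @export
ground_truth <- function(spec) {
  lay <- spec_layout(spec)
  dom_ids <- unique(unlist(lapply(spec$elements, `[[`, "domain_id")))
  doms <- lapply(dom_ids, function(d) {
    idx <- which(vapply(spec$elements, function(e) identical(e$domain_id, d),
                        logical(1)))
    domain_call(d, residue_ranges(lay$start[idx], lay$end[idx]),
                label = d, split = length(idx) > 1L)
  })
  link <- which(lay$kind == "linker")
  pairs <- do.call(rbind, lapply(spec$assemblies, function(a) {
    cmb <- utils::combn(sort(a), 2)
    data.frame(domain_a = cmb[1, ], domain_b = cmb[2, ])
  }))
  if (is.null(pairs)) pairs <- data.frame(domain_a = character(),
                                          domain_b = character())
  list(architecture = architecture(spec$entry_id, spec$length, domains = doms,
                                   disordered = residue_ranges(lay$start[link],
                                                               lay$end[link])),
       contact_pairs = pairs,
       domain_ids = dom_ids)
}

# Self-avoiding step helper: propose up to `tries` random 3.8 A steps from
# `cur`, optionally steered toward `target` and confined to a sphere; return
# the first acceptable point, or the best-separated fallback above 2.5 A.
#' @noRd
next_point <- function(cur, prev_pts, steer = NULL, centre = NULL,
                       radius = Inf, tries = 200L, min_clash = 3.0) {
  best <- NULL; best_d <- -Inf
  for (k in seq_len(tries)) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    if (!is.null(steer)) {
      dir <- steer / max(sqrt(sum(steer^2)), 1e-9)
      u <- 0.6 * dir + 0.4 * u
      u <- u / sqrt(sum(u^2))
    }
    cand <- cur + 3.8 * u
    if (!is.null(centre) && sqrt(sum((cand - centre)^2)) > radius) next
    dmin <- if (nrow(prev_pts)) min(sqrt(rowSums((prev_pts -
      matrix(cand, nrow(prev_pts), 3, byrow = TRUE))^2))) else Inf
    if (dmin >= min_clash) return(cand)
    if (dmin > best_d) { best_d <- dmin; best <- cand }
  }
  if (!is.null(best) && best_d > min_clash - 0.5) return(best)
  NULL  # cornered: the caller restarts this element's walk
}

#' Generate a synthetic C-alpha model with planted truth
#'
#' Builds a C-alpha trace with 3.8 A virtual bonds: each domain is a
#' self-avoiding random walk confined to a sphere of radius `2.5 * L^(1/3)` A
#' (L = total domain length, so both parts of a split domain share one
#' sphere), linkers are extended self-avoiding walks steered towards the next
#' domain's sphere. The pLDDT profile is Normal(88, plddt_sigma) inside
#' domains and Normal(40, 5/3 * plddt_sigma) in linkers, with a 3-residue
#' linear taper across boundaries, clipped to [0, 100]. Deterministic given
#' the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `model` (a [structure_model()]) and `truth`
#'   (see [ground_truth()]).
#' @export
generate_model <- function(spec) {
  lay <- spec_layout(spec)
  dom_ids <- unique(lay$domain[!is.na(lay$domain)])
  dom_len <- vapply(dom_ids, function(d) sum(lay$domain == d, na.rm = TRUE),
                    integer(1))
  radius <- 2.5 * dom_len^(1 / 3)
  names(radius) <- dom_ids
  # domain sphere centres spaced along x so spheres cannot overlap
  centres <- matrix(0, length(dom_ids), 3,
                    dimnames = list(dom_ids, c("x", "y", "z")))
  xc <- 0
  for (k in seq_along(dom_ids)) {
    if (k > 1L) xc <- xc + radius[k - 1L] + radius[k] + 6
    centres[k, 1] <- xc
  }
  with_seed(spec$seed, {
    n <- spec$length
    pts <- matrix(NA_real_, n, 3)
    cur <- NULL
    prev_ctr <- NULL; prev_rad <- 0
    for (i in seq_along(spec$elements)) {
      el <- spec$elements[[i]]
      rng <- lay$start[i]:lay$end[i]
      is_dom <- el$kind == "domain"
      if (is_dom) {
        ctr <- centres[el$domain_id, ]
        rad <- radius[el$domain_id]
      } else {
        # linkers escape the previous domain's sphere, then steer towards
        # the next domain element's sphere centre
        later <- which(lay$kind == "domain" & seq_along(spec$elements) > i)
        if (length(later)) {
          target <- centres[spec$elements[[later[1]]]$domain_id, ]
          target_rad <- radius[spec$elements[[later[1]]]$domain_id]
        } else {
          target <- (cur %||% c(0, 0, 0)) + c(1000, 0, 0)
          target_rad <- 0
        }
      }
      entry <- cur
      placed <- FALSE
      for (attempt in 1:40) {
        # a cornered walk restarts this element; late attempts relax the
        # clash floor a little so dense confined walks always terminate
        clash <- 3.0 - 0.8 * (attempt - 1) / 39
        cur <- entry
        stuck <- FALSE
        for (r in rng) {
          if (is.null(cur)) {
            pts[r, ] <- if (is_dom) ctr
              else c(-3.8 * (length(rng) - match(r, rng)), 0, 0)
          } else {
            prev <- pts[seq_len(max(0L, r - 2L)), , drop = FALSE]
            if (is_dom) {
              inside <- sqrt(sum((cur - ctr)^2)) <= rad
              p <- next_point(cur, prev,
                              steer = if (inside) NULL else ctr - cur,
                              centre = if (inside) ctr else NULL,
                              radius = rad, min_clash = clash)
            } else {
              steer <- if (!is.null(prev_ctr) &&
                           sqrt(sum((cur - prev_ctr)^2)) < prev_rad + 2)
                cur - prev_ctr
              else if (sqrt(sum((cur - target)^2)) < target_rad)
                NULL  # already inside the next sphere: wander freely
              else target - cur
              p <- next_point(cur, prev, steer = steer, min_clash = clash)
            }
            if (is.null(p)) { stuck <- TRUE; break }
            pts[r, ] <- p
          }
          cur <- pts[r, ]
        }
        if (!stuck) { placed <- TRUE; break }
      }
      if (!placed)
        stop("generation error: self-avoiding placement failed after bounded retries")
      if (is_dom) { prev_ctr <- ctr; prev_rad <- rad }
    }
    base <- ifelse(is.na(lay$domain), 40, 88)
    padded <- c(rep(base[1], 3), base, rep(base[n], 3))
    tapered <- stats::filter(padded, rep(1 / 7, 7), sides = 2)[4:(n + 3)]
    sigma <- ifelse(is.na(lay$domain), spec$noise$plddt_sigma * 5 / 3,
                    spec$noise$plddt_sigma)
    plddt <- pmin(pmax(tapered + stats::rnorm(n, 0, sigma), 0), 100)
    seqc <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                         n, replace = TRUE), collapse = "")
    model <- structure_model(spec$entry_id, "A", seq_len(n), seqc, pts, plddt)
    list(model = model, truth = ground_truth(spec))
  })
}

#' Generate a synthetic PAE matrix
#'
#' Plants the canonical visual features of a real predicted-aligned-error
#' matrix: dark low-error squares over rigid units (about 3 A within one
#' domain, about 6 A between distinct domains of one declared assembly), a
#' high-error background that grows with sequence separation
#' (`12 + 0.05 |i - j|` A) for any pair involving a linker residue or
#' domains that are mobile relative to each other, and the near-diagonal
#' low-error band (`|i - j| <= 4` capped at 4 A) that is always present in
#' real matrices. Noise is drawn independently for (i, j) and (j, i), so the
#' output is asymmetric like real PAE; values are clipped to [0, 31.75] and
#' the diagonal is zero. Deterministic given the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [pae_matrix()].
#' @export
generate_pae <- function(spec) {
  lay <- spec_layout(spec)
  n <- spec$length
  dom <- lay$domain
  asm <- rep(NA_integer_, n)
  for (k in seq_along(spec$assemblies))
    asm[dom %in% spec$assemblies[[k]]] <- k
  # domains outside any declared assembly are their own singleton assembly
  solo <- !is.na(dom) & is.na(asm)
  asm[solo] <- length(spec$assemblies) + as.integer(factor(dom[solo]))
  with_seed(spec$seed + 1L, {
    sep <- abs(outer(seq_len(n), seq_len(n), "-"))
    same_dom <- outer(dom, dom, function(a, b) !is.na(a) & !is.na(b) & a == b)
    same_asm <- outer(asm, asm, function(a, b) !is.na(a) & !is.na(b) & a == b)
    base <- 12 + 0.05 * sep
    sd <- matrix(2 * spec$noise$pae_sigma, n, n)
    base[same_asm & !same_dom] <- 6
    sd[same_asm & !same_dom] <- spec$noise$pae_sigma
    base[same_dom] <- 3
    sd[same_dom] <- spec$noise$pae_sigma
    vals <- base + matrix(stats::rnorm(n * n), n, n) * sd
    band <- sep <= 4 & sep > 0
    vals[band] <- pmin(vals[band], 4)
    vals <- pmin(pmax(vals, 0), 31.75)
    diag(vals) <- 0
    pae_matrix(vals, max_value = 31.75)
  })
}

#' Generate synthetic crosspeak-intensity profiles
#'
#' Emulates per-residue backbone amide signal intensities from TROSY spectra
#' of a protein in a free and a ligand-bound state. Free-state intensities
#' are about 1 for every residue (independently tumbling small domains and
#' linkers give sharp peaks). In the bound state, residues of immobilized
#' domains are scaled by a per-domain factor drawn U(0.05, 0.15) (signals
#' broadened away by slow tumbling of the rigid particle), all other
#' elements by U(0.8, 1.0). Both states carry multiplicative log-normal
#' noise; 10% of residues are masked `NA` (unassigned), chosen uniformly.
#' Deterministic given the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @param immobilized Character vector of domain ids incorporated into the
#'   bound rigid particle (subset of the spec's domain ids).
#' @return Data frame with columns `residue`, `intensity_free`,
#'   `intensity_bound`.
#' @export
generate_intensity_profiles <- function(spec, immobilized = character()) {
  lay <- spec_layout(spec)
  dom_ids <- unique(lay$domain[!is.na(lay$domain)])
  if (!all(immobilized %in% dom_ids))
    stop("immobilized must be a subset of the spec's domain ids")
  n <- spec$length
  with_seed(spec$seed + 2L, {
    dom_factor <- stats::setNames(
      ifelse(dom_ids %in% immobilized,
             stats::runif(length(dom_ids), 0.05, 0.15),
             stats::runif(length(dom_ids), 0.8, 1.0)),
      dom_ids)
    scale <- rep(NA_real_, n)
    for (i in seq_along(spec$elements)) {
      rng <- lay$start[i]:lay$end[i]
      d <- spec$elements[[i]]$domain_id
      scale[rng] <- if (is.null(d)) stats::runif(1, 0.8, 1.0) else dom_factor[d]
    }
    s <- spec$noise$intensity_sigma
    free <- exp(stats::rnorm(n, 0, s))
    bound <- scale * exp(stats::rnorm(n, 0, s))
    masked <- sample.int(n, size = round(0.1 * n))
    free[masked] <- NA
    bound[masked] <- NA
    data.frame(residue = seq_len(n), intensity_free = free,
               intensity_bound = bound)
  })
}

#' Write the full synthetic bundle for one spec
#'
#' Writes `<prefix>.pdb` (C-alpha model with pLDDT in the B-factor column),
#' `<prefix>.pae.json` (AFDB-dialect PAE), `<prefix>.truth.json` (planted
#' architecture plus contact pairs) and `<prefix>.intensity.tsv`.
#'
#' @param spec A [synthetic_spec()].
#' @param prefix Output path prefix.
#' @param immobilized Domain ids immobilized in the bound intensity state.
#' @return Invisibly, the named vector of written paths.
#' @export
simulate_bundle <- function(spec, prefix, immobilized = character()) {
  gen <- generate_model(spec)
  paths <- c(model = paste0(prefix, ".pdb"),
             pae = paste0(prefix, ".pae.json"),
             architecture = paste0(prefix, ".truth.arch.json"),
             truth = paste0(prefix, ".truth.json"),
             intensity = paste0(prefix, ".intensity.tsv"))
  write_structure_model(gen$model, paths["model"])
  write_pae(generate_pae(spec), paths["pae"])
  write_architecture(gen$truth$architecture, paths["architecture"])
  jsonlite::write_json(list(contact_pairs = gen$truth$contact_pairs,
                            immobilized_in_bound = immobilized,
                            seed = spec$seed),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  write_intensity_table(generate_intensity_profiles(spec, immobilized),
                        paths["intensity"])
  invisible(paths)
}
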