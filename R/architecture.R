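ARCHITECTURE_SCHEMA <- "afdomains.architecture/1"

#' Domain call
#'
#' One called domain: an ordered set of non-overlapping residue ranges (two
#' or more ranges mean the domain is "split" at the sequence level, i.e. one
#' spatial unit interrupted by a long insertion), a homology label (or
#' `"unassigned"`), and, when labelled against a reference structure, the
#' core superposition RMSD and core atom count.
#'
#' @param domain_id Stable identifier for the call (e.g. `"D1"`).
#' @param ranges Data frame with integer columns `start`, `end` (1-based,
#'   inclusive), sequence-ordered and non-overlapping.
#' @param label Homology label, default `"unassigned"`.
#' @param label_rmsd Core RMSD (A) against the labelling reference, or `NULL`.
#' @param label_core_atoms Core C-alpha count of that superposition, or `NULL`.
#' @param split Logical split flag (set by [detect_split_domains()]).
#' @return An object of class `"domain_call"`. `part_fractions` holds each
#'   range's exact share of the domain length (sums to 1).
#' @export
domain_call <- function(domain_id, ranges, label = "unassigned",
                        label_rmsd = NULL, label_core_atoms = NULL,
                        split = FALSE) {
  ranges <- residue_ranges(ranges$start, ranges$end)
  if (nrow(ranges) < 1L) stop("a domain call needs at least one residue range")
  o <- order(ranges$start)
  ranges <- ranges[o, , drop = FALSE]
  rownames(ranges) <- NULL
  if (nrow(ranges) > 1L && any(ranges$start[-1] <= ranges$end[-nrow(ranges)]))
    stop("domain call ranges overlap")
  w <- range_width(ranges)
  structure(list(domain_id = as.character(domain_id),
                 ranges = ranges,
                 label = as.character(label),
                 label_rmsd = label_rmsd,
                 label_core_atoms = label_core_atoms,
                 split = isTRUE(split),
                 part_fractions = w / sum(w)),
            class = "domain_call")
}

#' Display fractions rounded to quarters
#'
#' Formats exact part fractions of a split domain for diagram display using
#' the convention of approximate quarters (e.g. a 0.75/0.25 split displays as
#' three-quarters and one-quarter glyphs). The stored exact fractions are never altered;
#' this is presentation only.
#'
#' @param fractions Numeric vector of part fractions (each in (0, 1]).
#' @return Character vector of the same length; a fraction rounding to 4/4
#'   displays as `""` (whole domain).
#' @export
fraction_display <- function(fractions) {
  q <- pmin(pmax(round(fractions * 4), 1L), 4L)
  c("\u00bc", "\u00bd", "\u00be", "")[q]
}

#' Domain architecture
#'
#' The machine-readable form of a domain-architecture diagram: ordered domain
#' calls, disordered regions and interdomain contact calls for one chain.
#' Domain ranges and disordered ranges must jointly tile residues `1..length`
#' with no overlap (structured but unlabelled connectors are carried as
#' `"unassigned"` domain calls).
#'
#' @param entry_id Entry identifier.
#' @param length Chain length in residues.
#' @param domains List of [domain_call()] objects.
#' @param disordered Data frame of disordered ranges (`start`, `end`).
#' @param contacts Data frame of contact calls (`domain_a`, `domain_b`,
#'   `score`, `is_contact`), possibly empty.
#' @return An object of class `"architecture"`.
#' @export
architecture <- function(entry_id, length, domains = list(),
                         disordered = residue_ranges(), contacts = NULL) {
  length <- as.integer(length)
  if (length < 1L) stop("architecture length must be >= 1")
  if (!all(vapply(domains, inherits, logical(1), "domain_call")))
    stop("domains must be a list of domain_call objects")
  disordered <- residue_ranges(disordered$start, disordered$end)
  if (is.null(contacts))
    contacts <- data.frame(domain_a = character(), domain_b = character(),
                           score = numeric(), is_contact = logical())
  all_ranges <- rbind(do.call(rbind, c(lapply(domains, `[[`, "ranges"),
                                       list(residue_ranges()))),
                      disordered)
  assert_tiling(all_ranges, length, "domain and disordered ranges")
  structure(list(entry_id = as.character(entry_id),
                 length = length,
                 domains = domains,
                 disordered = disordered,
                 contacts = contacts),
            class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat(sprintf("<architecture> %s, %d residues, %d domain(s), %d disordered region(s), %d contact call(s)\n",
              x$entry_id, x$length, length(x$domains), nrow(x$disordered),
              sum(x$contacts$is_contact)))
  for (d in x$domains) {
    rng <- paste(sprintf("%d-%d", d$ranges$start, d$ranges$end), collapse = " + ")
    cat(sprintf("  %-6s %-12s %s%s\n", d$domain_id, d$label, rng,
                if (d$split) "  [split]" else ""))
  }
  invisible(x)
}

#' Write an architecture to versioned JSON
#'
#' @param arch An [architecture()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_architecture <- function(arch, path) {
  if (!inherits(arch, "architecture")) stop("arch must be an architecture")
  doms <- lapply(arch$domains, function(d) {
    list(domain_id = d$domain_id,
         label = d$label,
         ranges = lapply(seq_len(nrow(d$ranges)), function(i)
           list(start = d$ranges$start[i], end = d$ranges$end[i])),
         split = d$split,
         part_fractions = as.list(d$part_fractions),
         label_rmsd = d$label_rmsd,
         label_core_atoms = d$label_core_atoms)
  })
  dis <- lapply(seq_len(nrow(arch$disordered)), function(i)
    list(start = arch$disordered$start[i], end = arch$disordered$end[i]))
  cts <- lapply(seq_len(nrow(arch$contacts)), function(i)
    list(domain_a = arch$contacts$domain_a[i],
         domain_b = arch$contacts$domain_b[i],
         score = arch$contacts$score[i],
         is_contact = arch$contacts$is_contact[i]))
  jsonlite::write_json(list(schema = ARCHITECTURE_SCHEMA,
                            entry_id = arch$entry_id,
                            length = arch$length,
                            domains = doms,
                            disordered = dis,
                            contacts = cts),
                       path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read an architecture from versioned JSON
#'
#' @param path Path to a JSON file written by [write_architecture()].
#' @return An [architecture()].
#' @export
read_architecture <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(js$schema, ARCHITECTURE_SCHEMA))
    stop("unsupported architecture schema: ",
         js$schema %||% "<missing>", " (expected ", ARCHITECTURE_SCHEMA, ")")
  doms <- lapply(js$domains, function(d) {
    rng <- residue_ranges(vapply(d$ranges, `[[`, numeric(1), "start"),
                          vapply(d$ranges, `[[`, numeric(1), "end"))
    domain_call(d$domain_id, rng, label = d$label,
                label_rmsd = d$label_rmsd,
                label_core_atoms = d$label_core_atoms,
                split = isTRUE(d$split))
  })
  dis <- if (length(js$disordered))
    residue_ranges(vapply(js$disordered, `[[`, numeric(1), "start"),
                   vapply(js$disordered, `[[`, numeric(1), "end"))
  else residue_ranges()
  cts <- if (length(js$contacts))
    data.frame(domain_a = vapply(js$contacts, `[[`, character(1), "domain_a"),
               domain_b = vapply(js$contacts, `[[`, character(1), "domain_b"),
               score = vapply(js$contacts, `[[`, numeric(1), "score"),
               is_contact = vapply(js$contacts, `[[`, logical(1), "is_contact"))
  else NULL
  architecture(js$entry_id, js$length, domains = doms, disordered = dis,
               contacts = cts)
}

#' Compare two architectures of the same chain
#'
#' Matches domains between `arch` and `reference` by best residue-set overlap
#' (Jaccard index, greedy mutual matching), then scores boundary agreement.
#' A reference domain counts as being in agreement when it is matched, the
#' matched call has the same number of ranges, and every corresponding range
#' boundary differs by at most `slack` residues.
#'
#' @param arch Architecture under evaluation.
#' @param reference Reference architecture (same chain length).
#' @param slack Allowed boundary deviation in residues.
#' @return An object of class `"architecture_diff"`: a list with a per-domain
#'   `matches` data frame, `n_extra` (called domains with no reference
#'   partner), and `agreement` (fraction of reference domains in agreement).
#' @export
compare_architecture <- function(arch, reference, slack = 5L) {
  if (arch$length != reference$length)
    stop("architectures describe chains of different length")
  res_set <- function(d) range_residues(d$ranges)
  A <- lapply(arch$domains, res_set)
  R <- lapply(reference$domains, res_set)
  jac <- matrix(0, length(R), length(A))
  if (length(R) && length(A))
    for (i in seq_along(R)) for (j in seq_along(A))
      jac[i, j] <- length(intersect(R[[i]], A[[j]])) /
        length(union(R[[i]], A[[j]]))
  matches <- data.frame(ref_id = vapply(reference$domains, `[[`, character(1),
                                        "domain_id"),
                        matched_id = NA_character_,
                        jaccard = NA_real_,
                        max_boundary_delta = NA_real_,
                        agree = FALSE,
                        stringsAsFactors = FALSE)
  used <- rep(FALSE, length(A))
  if (length(R) && length(A)) {
    repeat {
      jac_open <- jac
      jac_open[!is.na(matches$matched_id), ] <- NA
      jac_open[, used] <- NA
      if (all(is.na(jac_open)) || max(jac_open, na.rm = TRUE) <= 0) break
      idx <- which(jac_open == max(jac_open, na.rm = TRUE), arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
      i <- idx[1]; j <- idx[2]
      used[j] <- TRUE
      matches$matched_id[i] <- arch$domains[[j]]$domain_id
      matches$jaccard[i] <- jac[i, j]
      rr <- reference$domains[[i]]$ranges
      ar <- arch$domains[[j]]$ranges
      if (nrow(rr) == nrow(ar)) {
        delta <- max(abs(rr$start - ar$start), abs(rr$end - ar$end))
        matches$max_boundary_delta[i] <- delta
        matches$agree[i] <- delta <= slack
      } else {
        matches$max_boundary_delta[i] <- Inf
      }
    }
  }
  structure(list(matches = matches,
                 n_extra = sum(!used),
                 n_missing = sum(is.na(matches$matched_id)),
                 agreement = if (nrow(matches)) mean(matches$agree) else 1,
                 slack = as.integer(slack)),
            class = "architecture_diff")
}

#' @export
print.architecture_diff <- function(x, ...) {
  cat(sprintf("<architecture_diff> agreement %.1f%% (slack %d): %d/%d reference domains matched, %d extra\n",
              100 * x$agreement, x$slack,
              sum(!is.na(x$matches$matched_id)), nrow(x$matches), x$n_extra))
  print(x$matches, row.names = FALSE)
  invisible(x)
}
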