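#' Pipeline configuration
#'
#' Collects every tunable of the annotation pipeline in one object. Defaults:
#' pLDDT cutoff 70 (the conventional low-confidence boundary of the AFDB
#' colour scale), smoothing window 9, minimum structured run 10, absorbed
#' disorder gap 4; PAE refinement gain 5 A with 25-residue sub-segments;
#' dendrogram cuts at 5 A (domain) and 10 A (assembly); contact threshold
#' 12 A; min-mode symmetrization; split-domain insertions of at least 30
#' residues.
#'
#' @param plddt_cutoff,window,min_struct,min_gap Segmentation parameters,
#'   see [segment_disorder()].
#' @param split_gain,min_subsegment PAE refinement parameters, see
#'   [refine_segments_with_pae()].
#' @param tau_domain,tau_assembly Dendrogram cut heights (A), see
#'   [rigid_assemblies()].
#' @param tau_contact Contact threshold (A), see [contact_matrix()].
#' @param symmetrize PAE symmetrization mode, `"min"` or `"mean"`.
#' @param min_insertion Split-domain insertion threshold (residues).
#' @return A list of class `"annotate_config"`.
#' @export
annotate_config <- function(plddt_cutoff = 70, window = 9L, min_struct = 10L,
                            min_gap = 4L, split_gain = 5, min_subsegment = 25L,
                            tau_domain = 5, tau_assembly = 10,
                            tau_contact = 12, symmetrize = c("min", "mean"),
                            min_insertion = 30L) {
  structure(list(plddt_cutoff = plddt_cutoff, window = as.integer(window),
                 min_struct = as.integer(min_struct),
                 min_gap = as.integer(min_gap),
                 split_gain = split_gain,
                 min_subsegment = as.integer(min_subsegment),
                 tau_domain = tau_domain, tau_assembly = tau_assembly,
                 tau_contact = tau_contact,
                 symmetrize = match.arg(symmetrize),
                 min_insertion = as.integer(min_insertion)),
            class = "annotate_config")
}

#' Infer a domain architecture from a model and its PAE matrix
#'
#' The end-to-end pipeline: confidence-profile segmentation
#' ([segment_disorder()]) -> PAE change-point refinement
#' ([refine_segments_with_pae()]) -> rigidity clustering into nested domain
#' and assembly units ([rigid_assemblies()]) -> domain calls with
#' split-domain detection ([call_domains()], [detect_split_domains()]) ->
#' interdomain contact calls ([contact_matrix()]) -> an [architecture()].
#' An all-disordered chain yields an architecture with zero domains.
#'
#' @param model A [structure_model()].
#' @param pae A [pae_matrix()] of matching size.
#' @param config An [annotate_config()].
#' @return An `architecture`; the configuration used is attached as
#'   attribute `"params"` and the per-domain assembly membership as
#'   attribute `"assembly"`.
#' @export
annotate <- function(model, pae, config = annotate_config()) {
  n <- n_residues(model)
  if (n != nrow(pae$values))
    stop("model (", n, " residues) and PAE matrix (", nrow(pae$values),
         ") describe chains of different length")
  seg <- segment_disorder(model, config$plddt_cutoff, config$window,
                          config$min_struct, config$min_gap)
  seg <- refine_segments_with_pae(seg, pae, config$min_subsegment,
                                  config$split_gain, config$symmetrize)
  str_seg <- seg[seg$klass == "structured", , drop = FALSE]
  dis_seg <- seg[seg$klass == "disordered", , drop = FALSE]
  if (nrow(str_seg) == 0L) {
    arch <- architecture(model$entry_id, n, domains = list(),
                         disordered = residue_ranges(dis_seg$start, dis_seg$end))
    attr(arch, "params") <- config
    return(arch)
  }
  units <- rigid_assemblies(str_seg, pae, config$tau_domain,
                            config$tau_assembly, config$symmetrize)
  calls <- call_domains(units$domain, str_seg)
  calls <- detect_split_domains(calls, config$min_insertion)
  contacts <- contact_matrix(calls, pae, config$tau_contact, config$symmetrize)
  arch <- architecture(model$entry_id, n, domains = calls,
                       disordered = residue_ranges(dis_seg$start, dis_seg$end),
                       contacts = contacts)
  # map each domain call to its assembly-level unit
  seg_of_call <- vapply(calls, function(d) which(str_seg$start == d$ranges$start[1])[1],
                        integer(1))
  asm <- stats::setNames(units$assembly[seg_of_call],
                         vapply(calls, `[[`, character(1), "domain_id"))
  attr(arch, "params") <- config
  attr(arch, "assembly") <- asm
  arch
}

# deterministic colour for a domain label
#' @noRd
label_colour <- function(label) {
  palette <- c("#4e79a7", "#f28e2b", "#59a14f", "#e15759", "#b07aa1",
               "#76b7b2", "#edc948", "#9c755f", "#bab0ac", "#86bcb6")
  if (label == "unassigned") return("#ffffff")
  idx <- sum(utf8ToInt(label)) %% length(palette) + 1L
  palette[idx]
}

#' Render an architecture diagram as SVG
#'
#' Horizontal diagram in the style of family-overview figures: a dark grey
#' baseline scaled to the chain length carries labelled domain boxes;
#' split-domain parts are linked by a bracket above the boxes and prefixed
#' with their quarter fractions; approximate boundary residue numbers are
#' printed beneath. Output is plain deterministic SVG text: identical input
#' gives byte-identical files.
#'
#' @param arch An [architecture()].
#' @param path Output SVG path.
#' @return Invisibly, `path`.
#' @export
render_diagram <- function(arch, path) {
  W <- 900; H <- 130; mar <- 40
  sc <- (W - 2 * mar) / arch$length
  xpos <- function(r) mar + (r - 1) * sc
  y0 <- 60
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">', W, H, W, H),
           sprintf('<title>%s</title>', arch$entry_id),
           sprintf('<line x1="%.2f" y1="%d" x2="%.2f" y2="%d" stroke="#444444" stroke-width="3"/>',
                   xpos(1), y0, xpos(arch$length + 1), y0))
  for (d in arch$domains) {
    disp <- if (d$split) fraction_display(d$part_fractions) else
      rep("", nrow(d$ranges))
    if (d$split && nrow(d$ranges) > 1L) {
      yb <- y0 - 24
      x1 <- xpos(d$ranges$start[1]); x2 <- xpos(d$ranges$end[nrow(d$ranges)] + 1)
      out <- c(out, sprintf('<path d="M %.2f %.2f L %.2f %.2f L %.2f %.2f L %.2f %.2f" fill="none" stroke="#888888" stroke-width="1"/>',
                            x1, yb + 4, x1, yb, x2, yb, x2, yb + 4))
    }
    for (i in seq_len(nrow(d$ranges))) {
      x <- xpos(d$ranges$start[i])
      w <- (d$ranges$end[i] - d$ranges$start[i] + 1) * sc
      lab <- paste0(disp[i], d$label)
      out <- c(out,
               sprintf('<rect x="%.2f" y="%d" width="%.2f" height="28" fill="%s" stroke="#222222" stroke-width="1"/>',
                       x, y0 - 14, w, label_colour(d$label)),
               sprintf('<text x="%.2f" y="%d" font-size="10" font-family="sans-serif" text-anchor="middle">%s</text>',
                       x + w / 2, y0 + 4, lab),
               sprintf('<text x="%.2f" y="%d" font-size="8" font-family="sans-serif" text-anchor="middle" fill="#555555">%d</text>',
                       x, y0 + 30, d$ranges$start[i]),
               sprintf('<text x="%.2f" y="%d" font-size="8" font-family="sans-serif" text-anchor="middle" fill="#555555">%d</text>',
                       x + w, y0 + 30, d$ranges$end[i]))
    }
  }
  out <- c(out, '</svg>')
  writeLines(out, path)
  invisible(path)
}

#' Render an annotated PAE heat map as SVG
#'
#' Green-scale heat map of the (possibly down-binned) PAE matrix — dark for
#' low expected error, white for the ceiling — with grid lines at domain
#' boundaries and dashed orange boxes marking called contact blocks below
#' the diagonal only (the quasi-symmetric block above the diagonal is left
#' unmarked for clarity). Deterministic SVG text output.
#'
#' @param pae A [pae_matrix()].
#' @param arch The matching [architecture()] (same chain length).
#' @param path Output SVG path.
#' @param max_bins Down-binning limit per axis (default 200).
#' @return Invisibly, `path`.
#' @export
render_matrix <- function(pae, arch, path, max_bins = 200L) {
  n <- nrow(pae$values)
  if (n != arch$length)
    stop("PAE matrix (", n, ") and architecture (", arch$length,
         ") describe chains of different length")
  bins <- min(max_bins, n)
  # block means per bin
  idx <- ceiling(seq_len(n) / n * bins)
  m <- rowsum(pae$values, idx)
  m <- t(rowsum(t(m), idx))
  cnt <- as.numeric(table(idx))
  m <- m / outer(cnt, cnt)
  shade <- function(v) {
    t <- pmin(pmax(v / pae$max_value, 0), 1)
    sprintf("#%02x%02x%02x", round(20 + 235 * t), round(110 + 145 * t),
            round(50 + 205 * t))
  }
  size <- 600; mar <- 30
  px <- (size - 2 * mar) / bins
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">', size, size, size, size),
           sprintf('<title>%s PAE</title>', arch$entry_id))
  for (i in seq_len(bins)) {
    cols <- shade(m[i, ])
    out <- c(out, sprintf('<rect x="%.2f" y="%.2f" width="%.3f" height="%.3f" fill="%s"/>',
                          mar + (seq_len(bins) - 1) * px, mar + (i - 1) * px,
                          px + 0.05, px + 0.05, cols))
  }
  topx <- function(r) mar + (r - 1) / n * (size - 2 * mar)
  for (d in arch$domains) for (i in seq_len(nrow(d$ranges))) {
    for (b in c(d$ranges$start[i], d$ranges$end[i] + 1)) {
      out <- c(out,
               sprintf('<line x1="%.2f" y1="%d" x2="%.2f" y2="%d" stroke="#00000033" stroke-width="0.5"/>',
                       topx(b), mar, topx(b), size - mar),
               sprintf('<line x1="%d" y1="%.2f" x2="%d" y2="%.2f" stroke="#00000033" stroke-width="0.5"/>',
                       mar, topx(b), size - mar, topx(b)))
    }
  }
  cts <- arch$contacts[arch$contacts$is_contact, , drop = FALSE]
  ids <- vapply(arch$domains, `[[`, character(1), "domain_id")
  for (k in seq_len(nrow(cts))) {
    da <- arch$domains[[match(cts$domain_a[k], ids)]]
    db <- arch$domains[[match(cts$domain_b[k], ids)]]
    # below the diagonal: per range pair, columns = earlier range in
    # sequence, rows = later range
    for (i in seq_len(nrow(da$ranges))) for (j in seq_len(nrow(db$ranges))) {
      ra <- da$ranges[i, ]; rb <- db$ranges[j, ]
      xr <- if (ra$start <= rb$start) ra else rb
      yr <- if (ra$start <= rb$start) rb else ra
      out <- c(out, sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="none" stroke="#ff7f0e" stroke-width="1.5" stroke-dasharray="4,3"/>',
                            topx(xr$start), topx(yr$start),
                            topx(xr$end + 1) - topx(xr$start),
                            topx(yr$end + 1) - topx(yr$start)))
    }
  }
  out <- c(out, '</svg>')
  writeLines(out, path)
  invisible(path)
}
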