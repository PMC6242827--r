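#' Rule set for single-particle composition classification
#'
#' Thresholds (weight fractions) and gates for typing coarse-mode particles
#' from quantified elemental composition plus morphology. Defaults encode
#' the field's usual single-particle criteria: sodium above the ~3 wt%
#' EDX detection limit, a crustal (Al+Si+Fe) gate for mineral dust with Si
#' counted only when Al or Fe corroborates it (bare Si can be substrate
#' background), a phosphorus marker plus carbonaceous matrix for biological
#' particles, and a 1-6 um size window for intact fungal spores.
#'
#' @param na_min_wt Minimum Na weight fraction to call a particle
#'   sodium-containing (EDX detection limit). Default 0.03.
#' @param crustal_min_wt Minimum Al+Si+Fe weight fraction for dust. Default 0.10.
#' @param p_min_wt Minimum P weight fraction for the biological gate. Default 0.005.
#' @param cno_min_wt Minimum C+N+O weight fraction for the biological gate.
#'   Default 0.50.
#' @param s_min_wt Minimum S weight fraction for sulfate. Default 0.05.
#' @param co_min_wt Minimum C+O weight fraction for purely carbonaceous
#'   particles. Default 0.90.
#' @param trace_min_wt Corroboration threshold: Si counts as crustal only when
#'   Al or Fe reaches this weight fraction; Al+Fe at this level upgrades a
#'   biological particle to mixed biological-dust. Default 0.01.
#' @param spore_size_um Length-2 numeric, the area-equivalent diameter window
#'   (um) for intact spores. Default c(1, 6).
#' @return An object of class `"ruleset"` (a named list).
#' @export
classification_rules <- function(na_min_wt = 0.03, crustal_min_wt = 0.10,
                                 p_min_wt = 0.005, cno_min_wt = 0.50,
                                 s_min_wt = 0.05, co_min_wt = 0.90,
                                 trace_min_wt = 0.01,
                                 spore_size_um = c(1, 6)) {
  thr <- c(na_min_wt = na_min_wt, crustal_min_wt = crustal_min_wt,
           p_min_wt = p_min_wt, cno_min_wt = cno_min_wt,
           s_min_wt = s_min_wt, co_min_wt = co_min_wt,
           trace_min_wt = trace_min_wt)
  if (any(thr <= 0) || any(thr >= 1)) {
    stop("all thresholds must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(length(spore_size_um) == 2L, spore_size_um[1] < spore_size_um[2])
  structure(c(as.list(thr), list(spore_size_um = spore_size_um)),
            class = "ruleset")
}

#' @export
print.ruleset <- function(x, ...) {
  cat("Particle classification rule set (weight-fraction thresholds):\n")
  for (nm in setdiff(names(x), "spore_size_um")) {
    cat(sprintf("  %-15s %.3f\n", nm, x[[nm]]))
  }
  cat(sprintf("  %-15s [%g, %g] um\n", "spore_size_um",
              x$spore_size_um[1], x$spore_size_um[2]))
  invisible(x)
}

#' Morphology labels accepted in particle records
#' @export
morphology_levels <- c("spherical", "rod-like", "spheroidal",
                       "irregular", "aggregate")

# weight-fraction lookup tolerant of absent elements
.wt <- function(w, el) {
  v <- w[el]
  v[is.na(v)] <- 0
  unname(v)
}

#' Flag sodium-containing particles
#'
#' A particle is sodium-containing when its Na weight fraction reaches the
#' EDX minimum detection limit (default 3 wt%). This flag defines the
#' "sodium salt particle" population used by the budget apportionment;
#' it is deliberately distinct from the Na-rich *composition class*, which
#' additionally requires Na to dominate the non-CNO elements.
#'
#' @param weight_fractions Named numeric vector of weight fractions, or a
#'   particle-table row's composition.
#' @param rules A [classification_rules()] object.
#' @return Logical scalar.
#' @export
flag_sodium_containing <- function(weight_fractions,
                                   rules = classification_rules()) {
  .wt(weight_fractions, "Na") >= rules$na_min_wt
}

#' Flag fungal spores from morphology, size and composition
#'
#' Intact fungal spores are identified by characteristic morphology
#' (spherical, rod-like or spheroidal), area-equivalent diameter within the
#' spore size window (default 1-6 um), a predominantly carbonaceous matrix
#' (C+N+O weight at least `cno_min_wt`) and detectable phosphorus
#' (biological marker, at least `p_min_wt`).
#'
#' @param morphology Morphology label, one of [morphology_levels].
#' @param diameter_um Area-equivalent diameter (um).
#' @param weight_fractions Named numeric vector of weight fractions.
#' @param rules A [classification_rules()] object.
#' @return Logical scalar.
#' @export
flag_fungal_spore <- function(morphology, diameter_um, weight_fractions,
                              rules = classification_rules()) {
  morphology <- match.arg(morphology, morphology_levels)
  morphology %in% c("spherical", "rod-like", "spheroidal") &&
    diameter_um >= rules$spore_size_um[1] &&
    diameter_um <= rules$spore_size_um[2] &&
    (.wt(weight_fractions, "C") + .wt(weight_fractions, "N") +
       .wt(weight_fractions, "O")) >= rules$cno_min_wt &&
    .wt(weight_fractions, "P") >= rules$p_min_wt
}

#' Assign a composition class by precedence rules
#'
#' First matching rule wins:
#' 1. `na_rich` - Na at or above the detection limit and the largest weight
#'    fraction among elements other than C, N, O.
#' 2. `mixed_bio_dust` - biological composition gates (C+N+O and P) pass and
#'    Al+Fe at or above `trace_min_wt`.
#' 3. `dust` - crustal weight (Al + Fe, plus Si only when corroborated by Al
#'    or Fe at `trace_min_wt`) at or above `crustal_min_wt`.
#' 4. `sulfate` - S at or above `s_min_wt`.
#' 5. `carbonaceous` - C+O at or above `co_min_wt`.
#' 6. `other` - anything else; the scheme is total.
#'
#' Cu is removed (with renormalization) before any rule is evaluated: on Cu
#' mesh grids it is substrate background, not particle composition.
#'
#' @inheritParams flag_sodium_containing
#' @return Character scalar, one of `na_rich`, `mixed_bio_dust`, `dust`,
#'   `sulfate`, `carbonaceous`, `other`.
#' @export
assign_composition_class <- function(weight_fractions,
                                     rules = classification_rules()) {
  w <- weight_fractions
  if ("Cu" %in% names(w)) {
    w <- w[setdiff(names(w), "Cu")]
    if (sum(w) > 0) w <- w / sum(w)
  }
  na <- .wt(w, "Na")
  non_cno <- w[setdiff(names(w), c("C", "N", "O"))]
  if (na >= rules$na_min_wt &&
      (length(non_cno) == 0L || na >= max(non_cno))) {
    return("na_rich")
  }
  cno <- .wt(w, "C") + .wt(w, "N") + .wt(w, "O")
  alfe <- .wt(w, "Al") + .wt(w, "Fe")
  if (cno >= rules$cno_min_wt && .wt(w, "P") >= rules$p_min_wt &&
      alfe >= rules$trace_min_wt) {
    return("mixed_bio_dust")
  }
  crustal <- alfe +
    if (.wt(w, "Al") >= rules$trace_min_wt ||
        .wt(w, "Fe") >= rules$trace_min_wt) .wt(w, "Si") else 0
  if (crustal >= rules$crustal_min_wt) return("dust")
  if (.wt(w, "S") >= rules$s_min_wt) return("sulfate")
  if (.wt(w, "C") + .wt(w, "O") >= rules$co_min_wt) return("carbonaceous")
  "other"
}

#' Extract the composition matrix of a particle table
#'
#' @param particles Particle table from [gen_particle_table()] or read from
#'   CSV with the same schema (`af_<El>` atomic-fraction columns).
#' @return Numeric matrix, one row per particle, columns named by element.
#' @keywords internal
composition_matrix <- function(particles) {
  af_cols <- grep("^af_", names(particles), value = TRUE)
  if (length(af_cols) == 0L) {
    stop("particle table has no atomic-fraction (af_*) columns", call. = FALSE)
  }
  m <- as.matrix(particles[, af_cols, drop = FALSE])
  colnames(m) <- sub("^af_", "", af_cols)
  m
}

#' Classify every particle in a table
#'
#' Applies [assign_composition_class()], [flag_fungal_spore()] and
#' [flag_sodium_containing()] row-wise after converting atomic to weight
#' fractions. Classification is total and deterministic: every particle gets
#' exactly one composition class, and permuting input rows permutes the
#' output identically.
#'
#' @param particles Particle table (see [gen_particle_table()] for the schema).
#' @param rules A [classification_rules()] object.
#' @return Data frame with columns `particle_id`, `composition_class`,
#'   `is_fungal_spore`, `is_sodium_containing`, `sodium_salt_particle`
#'   (identical to `is_sodium_containing`, retained under the budget
#'   module's name for the population it apportions).
#' @export
classify_particles <- function(particles, rules = classification_rules()) {
  af <- composition_matrix(particles)
  n <- nrow(particles)
  cls <- character(n)
  spore <- logical(n)
  nacont <- logical(n)
  for (i in seq_len(n)) {
    a <- af[i, ]
    a <- a[a > 0]
    w <- atomic_to_weight(a / sum(a))
    cls[i] <- assign_composition_class(w, rules)
    spore[i] <- flag_fungal_spore(particles$morphology[i],
                                  particles$diameter_um[i], w, rules)
    nacont[i] <- flag_sodium_containing(w, rules)
  }
  data.frame(
    particle_id = particles$particle_id,
    composition_class = cls,
    is_fungal_spore = spore,
    is_sodium_containing = nacont,
    sodium_salt_particle = nacont,
    stringsAsFactors = FALSE
  )
}

#' Drop particles collected on grid edges
#'
#' Particles on the edges of the Cu mesh carry a high substrate background
#' and are excluded before any statistics (typically ~5-10% of detections).
#'
#' @param particles Particle table with a logical `on_grid_edge` column.
#' @param quiet Suppress the removal-count message.
#' @return The table without edge rows.
#' @export
exclude_edge_particles <- function(particles, quiet = FALSE) {
  stopifnot("on_grid_edge" %in% names(particles))
  drop <- particles$on_grid_edge
  if (!quiet) {
    message(sum(drop), " of ", nrow(particles),
            " particles on grid edge excluded")
  }
  particles[!drop, , drop = FALSE]
}

#' Per-group class number fractions with binomial standard errors
#'
#' For each grouping-variable combination and each class present, reports
#' fraction = class count / group size and SE = sqrt(p (1 - p) / n), the
#' binomial standard error attached to reported fractions such as
#' "60% +/- 2% biological below the canopy".
#'
#' @param results Classification results joined to particle metadata (any
#'   data frame holding `class_col` and the `group_keys`).
#' @param group_keys Character vector of grouping column names (e.g.
#'   `c("canopy", "period")`); `NULL` treats the whole table as one group.
#' @param class_col Column holding the class label. Default
#'   `"composition_class"`; any categorical or logical column works (e.g.
#'   `is_fungal_spore` for the biological fraction).
#' @return Data frame with columns `<group_keys>..., class, n_class, n,
#'   fraction, standard_error`.
#' @export
group_number_fractions <- function(results, group_keys = NULL,
                                   class_col = "composition_class") {
  stopifnot(class_col %in% names(results))
  if (is.null(group_keys)) {
    results$.group <- "all"
    group_keys <- ".group"
  }
  split_key <- interaction(results[group_keys], drop = TRUE, lex.order = TRUE)
  pieces <- split(results, split_key)
  out <- do.call(rbind, lapply(pieces, function(g) {
    n <- nrow(g)
    if (n == 0L) {
      warning("empty group omitted", call. = FALSE)
      return(NULL)
    }
    tab <- table(g[[class_col]])
    p <- as.numeric(tab) / n
    cbind(
      g[rep(1L, length(tab)), group_keys, drop = FALSE],
      data.frame(class = names(tab), n_class = as.integer(tab), n = n,
                 fraction = p, standard_error = sqrt(p * (1 - p) / n),
                 stringsAsFactors = FALSE)
    )
  }))
  rownames(out) <- NULL
  out[[".group"]] <- NULL
  out
}

#' Size distribution of a particle class
#'
#' Histogram of area-equivalent diameters for one class, with counts and
#' the size-distribution density dN/dlog10(D) conventional for aerosol
#' size spectra.
#'
#' @param particles Particle table (provides `diameter_um`).
#' @param results Classification results aligned with `particles` by
#'   `particle_id`.
#' @param class_label Composition class to select; an empty class yields a
#'   zero histogram.
#' @param bin_edges Strictly increasing numeric vector of diameter bin
#'   edges (um). Particles outside the edges are dropped from the histogram.
#' @return Data frame with `bin_lo`, `bin_hi`, `count`, `dN_dlogD`.
#' @export
size_distribution <- function(particles, results, class_label,
                              bin_edges = c(0.32, 0.56, 1, 1.8, 3.2, 5.6, 10)) {
  stopifnot(all(diff(bin_edges) > 0), length(bin_edges) >= 2L)
  merged <- merge(particles[, c("particle_id", "diameter_um")], results,
                  by = "particle_id")
  d <- merged$diameter_um[merged$composition_class == class_label]
  d <- d[d >= bin_edges[1] & d <= bin_edges[length(bin_edges)]]
  counts <- if (length(d) == 0L) {
    rep(0L, length(bin_edges) - 1L)
  } else {
    hist(d, breaks = bin_edges, plot = FALSE)$counts
  }
  dlog <- diff(log10(bin_edges))
  data.frame(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    count = counts,
    dN_dlogD = counts / dlog
  )
}
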