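# Connectivity masks: which synaptic / gap-junction entries may be nonzero.
#
# All weight matrices are indexed [postsynaptic, presynaptic]:
#   syn_nn : J x J  neuron  -> neuron chemical synapses
#   syn_nm : U x J  neuron  -> muscle
#   syn_mn : J x U  muscle  -> neuron (includes proprioceptive feedback)
#   syn_in : J x P  command -> neuron
#   gap_nn : J x J  symmetric, FALSE diagonal
#   gap_mn : J x U  neuron-muscle gap junctions (transpose implied)
#   gap_mm : U x U  symmetric, FALSE diagonal

new_connectome_mask <- function(syn_nn, syn_nm, syn_mn, syn_in,
                                gap_nn, gap_mn, gap_mm, map,
                                proprioceptive = NULL) {
  m <- structure(
    list(syn_nn = syn_nn, syn_nm = syn_nm, syn_mn = syn_mn, syn_in = syn_in,
         gap_nn = gap_nn, gap_mn = gap_mn, gap_mm = gap_mm, map = map,
         proprioceptive = proprioceptive),
    class = "connectome_mask"
  )
  validate_connectome_mask(m)
}

#' @export
print.connectome_mask <- function(x, ...) {
  cnt <- function(m) sum(m)
  cat("<connectome_mask> ", x$map$n_neurons, " neurons / ", x$map$n_muscles,
      " muscles\n  synapses: nn=", cnt(x$syn_nn), " nm=", cnt(x$syn_nm),
      " mn=", cnt(x$syn_mn), " in=", cnt(x$syn_in),
      "\n  gap junctions (directed entries): nn=", cnt(x$gap_nn),
      " mn=", cnt(x$gap_mn), " mm=", cnt(x$gap_mm), "\n", sep = "")
  invisible(x)
}

validate_connectome_mask <- function(m) {
  map <- m$map
  J <- map$n_neurons; U <- map$n_muscles; P <- map$n_commands
  stopifnot(
    identical(dim(m$syn_nn), c(J, J)), identical(dim(m$syn_nm), c(U, J)),
    identical(dim(m$syn_mn), c(J, U)), identical(dim(m$syn_in), c(J, P)),
    identical(dim(m$gap_nn), c(J, J)), identical(dim(m$gap_mn), c(J, U)),
    identical(dim(m$gap_mm), c(U, U))
  )
  if (!isTRUE(all(m$gap_nn == t(m$gap_nn))))
    abort("gap_nn mask must be symmetric.")
  if (!isTRUE(all(m$gap_mm == t(m$gap_mm))))
    abort("gap_mm mask must be symmetric.")
  if (any(diag(m$gap_nn)) || any(diag(m$gap_mm)))
    abort("no self gap junctions allowed (diagonal must be FALSE).")
  m
}

mask_dimnames <- function(mask) {
  map <- mask$map
  dimnames(mask$syn_nn) <- list(map$neuron_name, map$neuron_name)
  dimnames(mask$syn_nm) <- list(map$muscle_name, map$neuron_name)
  dimnames(mask$syn_mn) <- list(map$neuron_name, map$muscle_name)
  dimnames(mask$syn_in) <- list(map$neuron_name, map$command_name)
  dimnames(mask$gap_nn) <- list(map$neuron_name, map$neuron_name)
  dimnames(mask$gap_mn) <- list(map$neuron_name, map$muscle_name)
  dimnames(mask$gap_mm) <- list(map$muscle_name, map$muscle_name)
  mask
}

#' Proprioceptive feedback wiring
#'
#' Pairs each A-class neuron (DA, VA) with up to `S` muscles *anterior* to its
#' anchor segment and each B-class neuron (DB, VB) with up to `S` muscles
#' *posterior* to it, on both muscle rows of the neuron's side (dorsal classes
#' sense the two dorsal rows, ventral classes the two ventral rows).  At the
#' head and tail the span is clipped to the muscles that exist, so boundary
#' neurons receive fewer (possibly zero) feedback inputs.
#'
#' These pairs stand in for stretch-sensitive input: muscle activity is used
#' as a proxy for local body curvature because the model has no body.
#'
#' @param map A [neuron_index_map()].
#' @param S Feedback length in muscles per row (default 7).
#' @return A tibble with columns `neuron`, `muscle` (global indices), plus
#'   `class` and `segment` for readability.
#' @export
proprioceptive_wiring <- function(map, S = 7L) {
  S <- as.integer(S)
  if (S < 1L) abort("`S` must be at least 1.")
  out <- vector("list", map$n_neurons)
  for (i in seq_len(map$n_neurons)) {
    cls <- map$neuron_class[i]
    if (!cls %in% c("DA", "VA", "DB", "VB")) next
    a <- map$anchor_segment[i]
    segs <- if (cls %in% c("DA", "VA")) (a - S):(a - 1L) else (a + 1L):(a + S)
    segs <- segs[segs >= 1L & segs <= map$n_segments]
    if (length(segs) == 0L) next
    rows <- side_rows(map$neuron_side[i])
    mus <- which(map$muscle_row %in% rows & map$muscle_segment %in% segs)
    if (length(mus) == 0L) next
    out[[i]] <- tibble(neuron = i, muscle = mus, class = cls,
                       segment = map$muscle_segment[mus])
  }
  bind_rows(out)
}

#' Synthesize a connectome mask with the circuit's qualitative structure
#'
#' Generates connectivity masks that emulate the ventral-cord wiring pattern
#' without requiring the real adjacency tables: cholinergic neurons (DA, DB,
#' VA, VB, AS) synapse onto muscles of their side and onto the GABAergic
#' D-class; DD and VD synapse onto muscles of their side and back onto the
#' cholinergic classes; all connections are local, linking cells whose anchor
#' segments are at most `locality_span` segments apart.  Gap junctions are
#' symmetric: consecutive neurons within a class are chained, cross-class
#' neuron pairs with near-identical anchors are coupled, each muscle row
#' carries a nearest-neighbour chain (so activity can propagate along the
#' body), and neurons couple electrically to muscles at their anchor segment.
#' Muscle-to-neuron chemical entries are exactly the proprioceptive pairs of
#' [proprioceptive_wiring()].  Forward command inputs reach the B classes,
#' backward command inputs the A classes.
#'
#' With all densities 1 (the default) the mask is deterministic; densities
#' below 1 thin the synaptic blocks per presynaptic class, reproducibly under
#' `seed`.
#'
#' @param map A [neuron_index_map()].
#' @param density_per_class Named numeric in `[0,1]`: per presynaptic class,
#'   the probability that an allowed synaptic edge is kept.  A single unnamed
#'   number applies to all classes.
#' @param locality_span Maximum anchor-segment distance (in segments) for
#'   synaptic and neuron-neuron gap connections.
#' @param seed Integer seed used when any density is below 1.
#' @param S Proprioceptive feedback length passed to
#'   [proprioceptive_wiring()].
#' @param gap_mn_density Probability of keeping each neuron-muscle gap
#'   junction at the anchor segment.
#' @return A `connectome_mask`.
#' @export
synthesize_connectome <- function(map = neuron_index_map(),
                                  density_per_class = 1,
                                  locality_span = 3L,
                                  seed = NULL,
                                  S = 7L,
                                  gap_mn_density = 1) {
  if (locality_span < 1L) abort("`locality_span` must be >= 1.")
  if (length(density_per_class) == 1L && is.null(names(density_per_class))) {
    density_per_class <- setNames(rep(density_per_class, 7), MOTOR_CLASSES)
  }
  dens <- setNames(rep(1, 7), MOTOR_CLASSES)
  dens[names(density_per_class)] <- density_per_class
  if (any(dens < 0 | dens > 1)) abort("densities must be in [0, 1].")

  build <- function() {
    J <- map$n_neurons; U <- map$n_muscles; P <- map$n_commands
    anchor <- map$anchor_segment
    cls <- map$neuron_class
    side <- map$neuron_side

    near_nn <- abs(outer(anchor, anchor, "-")) <= locality_span
    chol <- cls %in% c("DA", "DB", "VA", "VB", "AS")
    gaba <- cls %in% c("DD", "VD")

    # chemical neuron->neuron: cholinergic -> D-class, D-class -> cholinergic
    allowed_nn <- (outer(gaba, chol, "&") | outer(chol, gaba, "&")) & near_nn
    diag(allowed_nn) <- FALSE

    # neuron->muscle: local, on the presynaptic neuron's side
    seg_m <- map$muscle_segment
    near_nm <- abs(outer(seg_m, anchor, "-")) <= locality_span
    same_side_nm <- outer(substr(map$muscle_row, 2, 2) == "D",
                          side == "D", "==")
    allowed_nm <- near_nm & same_side_nm

    keep <- function(m, pre_class) {
      p <- dens[pre_class]           # by presynaptic (column) class
      if (all(p == 1)) return(m)
      drop <- matrix(runif(length(m)) > rep(p, each = nrow(m)), nrow(m))
      m & !drop
    }
    syn_nn <- keep(allowed_nn, cls)
    syn_nm <- keep(allowed_nm, cls)

    # muscle->neuron chemical = proprioceptive pairs only
    prop <- proprioceptive_wiring(map, S = S)
    syn_mn <- matrix(FALSE, J, U)
    if (nrow(prop) > 0L) syn_mn[cbind(prop$neuron, prop$muscle)] <- TRUE

    # command inputs: forward -> B classes, backward -> A classes
    syn_in <- matrix(FALSE, J, P)
    syn_in[cls %in% c("DB", "VB"), map$forward_commands] <- TRUE
    syn_in[cls %in% c("DA", "VA"), map$backward_commands] <- TRUE

    # gap junctions
    gap_nn <- matrix(FALSE, J, J)
    for (cl in MOTOR_CLASSES) {       # chain consecutive ranks in a class
      idx <- class_indices(map, cl)
      if (length(idx) > 1L) {
        gap_nn[cbind(idx[-length(idx)], idx[-1L])] <- TRUE
      }
    }
    gap_nn <- gap_nn | (abs(outer(anchor, anchor, "-")) <= 1L &
                          outer(cls, cls, "!="))
    gap_nn <- gap_nn | t(gap_nn)
    diag(gap_nn) <- FALSE

    gap_mn <- abs(outer(anchor, seg_m, "-")) <= 1L &
      outer(side == "D", substr(map$muscle_row, 2, 2) == "D", "==")
    if (gap_mn_density < 1) {
      gap_mn <- gap_mn & (matrix(runif(J * U), J, U) <= gap_mn_density)
    }

    gap_mm <- matrix(FALSE, U, U)
    for (rw in MUSCLE_ROWS) {         # nearest-neighbour chain along rows
      idx <- row_indices(map, rw)
      gap_mm[cbind(idx[-length(idx)], idx[-1L])] <- TRUE
    }
    # couple the two rows of each side segment-wise (left/right move together)
    for (sd in c("D", "V")) {
      rws <- side_rows(sd)
      i1 <- row_indices(map, rws[1]); i2 <- row_indices(map, rws[2])
      k <- min(length(i1), length(i2))
      gap_mm[cbind(i1[seq_len(k)], i2[seq_len(k)])] <- TRUE
    }
    gap_mm <- gap_mm | t(gap_mm)
    diag(gap_mm) <- FALSE

    mask_dimnames(new_connectome_mask(
      syn_nn, syn_nm, syn_mn, syn_in, gap_nn, gap_mn, gap_mm, map,
      proprioceptive = prop))
  }

  gen <- function() {
    if (is.null(seed)) build() else withr::with_seed(seed, build())
  }
  m <- gen()
  # untrainable-target guard: every non-head muscle needs >= 1 synaptic input
  head_cut <- ceiling(map$n_segments / 3)
  body_rows_ok <- function(m) {
    body <- map$muscle_segment > head_cut
    all(rowSums(m$syn_nm[body, , drop = FALSE]) > 0)
  }
  tries <- 0L
  while (!body_rows_ok(m)) {
    tries <- tries + 1L
    if (tries > 20L || is.null(seed)) {
      abort(paste0("synthesized mask leaves a non-head muscle without ",
                   "synaptic input; increase density or locality_span."))
    }
    seed <- seed + 1000L
    m <- gen()
  }
  m
}

# ---------------------------------------------------------------------------
# Loading real adjacency tables (wormwiring dialect)

read_adjacency_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- read.table(x, header = TRUE, row.names = 1, sep = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
  }
  m <- as.matrix(x)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    abort("adjacency table needs cell names on both rows and columns.")
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0))
    abort("adjacency counts must be nonnegative numbers.")
  m
}

# resolve a cell name to (kind, index); kind in neuron/muscle/command/other
resolve_cell <- function(nm, map) {
  canon <- toupper(trimws(nm))
  # pad single-digit numeric suffix: DA1 -> DA01
  canon2 <- sub("^([A-Z]+)([0-9])$", "\\10\\2", canon)
  for (cand in unique(c(canon, canon2))) {
    i <- match(cand, map$neuron_name)
    if (!is.na(i)) return(list(kind = "neuron", index = i))
    i <- match(cand, map$muscle_name)
    if (!is.na(i)) return(list(kind = "muscle", index = i))
    i <- match(cand, map$command_name)
    if (!is.na(i)) return(list(kind = "command", index = i))
  }
  if (grepl("^[A-Z]{2,6}[0-9]{0,2}[LRDV]?$", canon)) {
    return(list(kind = "other", index = NA_integer_))
  }
  list(kind = "unresolvable", index = NA_integer_)
}

#' Build a connectome mask from adjacency tables
#'
#' Reads synaptic and gap-junction adjacency matrices in the wormwiring
#' dialect (delimiter-separated, header row and column of cell names, integer
#' contact counts, rows presynaptic and columns postsynaptic) and converts
#' them to boolean masks: an entry is allowed wherever the contact count is
#' positive.  Gap masks are symmetrized by logical OR; asymmetric gap counts
#' raise a warning.  Cells outside the model (neurons other than the seven
#' motor classes and the ten command interneurons) are dropped, and the
#' number dropped is reported as a message and in the
#' `dropped_cells` attribute.  Names that do not look like cell names at all
#' are a hard error.  Proprioceptive pairs are added to `syn_mn` on top of
#' any adjacency-derived muscle-to-neuron entries.
#'
#' @param syn_table,gap_table File path or data frame / matrix of counts.
#' @param map A [neuron_index_map()] (full size for real data).
#' @param S Proprioceptive feedback length.
#' @return A `connectome_mask` with attribute `dropped_cells`.
#' @export
load_adjacency <- function(syn_table, gap_table, map = neuron_index_map(),
                           S = 7L) {
  syn <- read_adjacency_table(syn_table)
  gap <- read_adjacency_table(gap_table)
  J <- map$n_neurons; U <- map$n_muscles; P <- map$n_commands

  syn_nn <- matrix(FALSE, J, J); syn_nm <- matrix(FALSE, U, J)
  syn_mn <- matrix(FALSE, J, U); syn_in <- matrix(FALSE, J, P)
  gap_nn <- matrix(FALSE, J, J); gap_mn <- matrix(FALSE, J, U)
  gap_mm <- matrix(FALSE, U, U)
  dropped <- character(0)

  resolve_all <- function(nms) {
    res <- lapply(nms, resolve_cell, map = map)
    bad <- nms[vapply(res, function(r) r$kind == "unresolvable", logical(1))]
    if (length(bad) > 0) {
      abort(paste0("unresolvable cell name(s): ",
                   paste(unique(bad), collapse = ", ")))
    }
    res
  }

  ingest <- function(tab, assign_fun) {
    pre <- resolve_all(rownames(tab))
    post <- resolve_all(colnames(tab))
    for (r in seq_len(nrow(tab))) {
      for (cidx in seq_len(ncol(tab))) {
        if (tab[r, cidx] <= 0) next
        assign_fun(pre[[r]], post[[cidx]])
      }
    }
    list(pre = pre, post = post)
  }

  note_drop <- function(...) dropped <<- c(dropped, ...)

  ingest(syn, function(pre, post) {
    if (pre$kind == "other" || post$kind == "other") {
      note_drop("syn"); return(invisible())
    }
    if (pre$kind == "neuron" && post$kind == "neuron") {
      syn_nn[post$index, pre$index] <<- TRUE
    } else if (pre$kind == "neuron" && post$kind == "muscle") {
      syn_nm[post$index, pre$index] <<- TRUE
    } else if (pre$kind == "muscle" && post$kind == "neuron") {
      syn_mn[post$index, pre$index] <<- TRUE
    } else if (pre$kind == "command" && post$kind == "neuron") {
      syn_in[post$index, pre$index] <<- TRUE
    } else {
      note_drop("syn")
    }
  })

  # gap table: check symmetry of counts on neuron/muscle cells we keep
  if (!isTRUE(all.equal(unname(gap[rownames(gap) %in% colnames(gap),
                                   colnames(gap) %in% rownames(gap)],
                               ),
                        unname(t(gap)[rownames(gap) %in% colnames(gap),
                                      colnames(gap) %in% rownames(gap)])))) {
    warn("asymmetric gap-junction counts; symmetrizing by logical OR.")
  }
  ingest(gap, function(pre, post) {
    if (pre$kind == "other" || post$kind == "other") {
      note_drop("gap"); return(invisible())
    }
    if (pre$kind == "neuron" && post$kind == "neuron") {
      gap_nn[post$index, pre$index] <<- TRUE
      gap_nn[pre$index, post$index] <<- TRUE
    } else if (pre$kind == "neuron" && post$kind == "muscle") {
      gap_mn[pre$index, post$index] <<- TRUE
    } else if (pre$kind == "muscle" && post$kind == "neuron") {
      gap_mn[post$index, pre$index] <<- TRUE
    } else if (pre$kind == "muscle" && post$kind == "muscle") {
      gap_mm[post$index, pre$index] <<- TRUE
      gap_mm[pre$index, post$index] <<- TRUE
    } else {
      note_drop("gap")
    }
  })
  diag(gap_nn) <- FALSE; diag(gap_mm) <- FALSE

  prop <- proprioceptive_wiring(map, S = S)
  if (nrow(prop) > 0L) syn_mn[cbind(prop$neuron, prop$muscle)] <- TRUE

  if (length(dropped) > 0) {
    message(length(dropped), " adjacency entr",
            if (length(dropped) == 1) "y" else "ies",
            " involving cells outside the model were dropped.")
  }
  m <- mask_dimnames(new_connectome_mask(
    syn_nn, syn_nm, syn_mn, syn_in, gap_nn, gap_mn, gap_mm, map,
    proprioceptive = prop))
  attr(m, "dropped_cells") <- length(dropped)
  m
}

# ---------------------------------------------------------------------------
# Plain-text (JSON) serialization

#' Write / read a connectome mask as JSON
#'
#' Masks are stored as a single JSON file: named boolean matrices plus the
#' index-map dimensions.  `read_connectome()` is the exact inverse of
#' `write_connectome()`.
#'
#' @param mask A `connectome_mask`.
#' @param path File path (`.json`).
#' @return `write_connectome()` returns `path` invisibly; `read_connectome()`
#'   returns a `connectome_mask`.
#' @export
write_connectome <- function(mask, path) {
  payload <- list(
    n_segments = mask$map$n_segments,
    class_sizes = as.list(setNames(mask$map$classes$size,
                                   mask$map$classes$class)),
    masks = lapply(mask[c("syn_nn", "syn_nm", "syn_mn", "syn_in",
                          "gap_nn", "gap_mn", "gap_mm")],
                   function(m) unname(m * 1L))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- unlist(payload$class_sizes)
  map <- neuron_index_map(payload$n_segments, class_sizes = sizes)
  mk <- lapply(payload$masks, function(m) matrix(as.logical(m), nrow(m)))
  prop <- proprioceptive_wiring(map)  # recomputed; deterministic given map
  mask_dimnames(new_connectome_mask(
    mk$syn_nn, mk$syn_nm, mk$syn_mn, mk$syn_in,
    mk$gap_nn, mk$gap_mn, mk$gap_mm, map, proprioceptive = prop))
}
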