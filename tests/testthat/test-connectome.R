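test_that("standard index map reproduces the ventral-cord conventions", {
  map <- neuron_index_map()
  expect_equal(map$n_neurons, 69L)
  expect_equal(map$n_muscles, 95L)
  expect_equal(map$n_commands, 10L)

  # class ranges: DA 1-8, DB 9-16, DD 17-22, VA 23-34, VB 35-45,
  # VD 46-58, AS 59-69
  expect_equal(unname(map$classes$from), c(1L, 9L, 17L, 23L, 35L, 46L, 59L))
  expect_equal(unname(map$classes$to), c(8L, 16L, 22L, 34L, 45L, 58L, 69L))

  # ranges are disjoint and cover 1..69 exactly
  all_idx <- unlist(lapply(seq_len(7), function(i) {
    map$classes$from[i]:map$classes$to[i]
  }))
  expect_equal(sort(all_idx), 1:69)

  # excitatory/inhibitory sets partition the neurons
  exc <- wormcpg:::excitatory_indices(map)
  inh <- wormcpg:::inhibitory_indices(map)
  expect_length(intersect(exc, inh), 0)
  expect_equal(sort(c(exc, inh)), 1:69)
  expect_setequal(unique(map$neuron_class[inh]), c("DD", "VD"))

  # muscle rows: LD 1-24, RD 25-48, LV 49-72, RV 73-95
  expect_equal(row_indices(map, "LD"), 1:24)
  expect_equal(row_indices(map, "RD"), 25:48)
  expect_equal(row_indices(map, "LV"), 49:72)
  expect_equal(row_indices(map, "RV"), 73:95)
  expect_equal(map$muscle_segment[73:95], 1:23)
})

test_that("scaled index maps keep the class structure", {
  map <- scaled_index_map(8)
  expect_equal(map$n_segments, 8L)
  expect_gte(map$n_neurons, 20L)
  expect_gte(map$n_muscles, 24L)
  expect_equal(length(map$classes$class), 7L)
  expect_true(all(map$anchor_segment >= 1 & map$anchor_segment <= 8))
})

test_that("proprioceptive wiring matches a brute-force enumeration", {
  map <- neuron_index_map()
  S <- 7L
  wiring <- proprioceptive_wiring(map, S = S)

  # independent enumeration, written directly from the wiring rule
  expected <- 0L
  for (i in seq_len(map$n_neurons)) {
    cls <- map$neuron_class[i]
    if (!cls %in% c("DA", "VA", "DB", "VB")) next
    a <- map$anchor_segment[i]
    n_seg <- if (cls %in% c("DA", "VA")) min(S, a - 1) else
      min(S, map$n_segments - a)
    rows <- if (cls %in% c("DA", "DB")) c("LD", "RD") else c("LV", "RV")
    for (rw in rows) {
      row_len <- sum(map$muscle_row == rw)
      segs <- if (cls %in% c("DA", "VA")) {
        seq_len(a - 1)[seq_len(a - 1) >= a - S]
      } else {
        intersect((a + 1):(a + S), seq_len(row_len))
      }
      expected <- expected + length(segs)
    }
  }
  expect_equal(nrow(wiring), expected)

  # B-class mid-body neuron senses exactly S posterior muscles per row
  db_mid <- which(map$neuron_class == "DB" & map$anchor_segment == 12)[1]
  w_db <- wiring[wiring$neuron == db_mid, ]
  expect_equal(nrow(w_db), 2L * S)
  expect_true(all(w_db$segment > map$anchor_segment[db_mid]))

  # A-class at the very head gets clipped
  map3 <- neuron_index_map(3)
  w3 <- proprioceptive_wiring(map3, S = 7)
  head_a <- which(map3$neuron_class %in% c("DA", "VA") &
                    map3$anchor_segment == 1)
  expect_true(all(!w3$neuron %in% head_a))
})

test_that("synthesized connectome has the qualitative circuit structure", {
  map <- neuron_index_map(6)
  m1 <- synthesize_connectome(map, density_per_class = 0.8,
                              locality_span = 2, seed = 42)
  m2 <- synthesize_connectome(map, density_per_class = 0.8,
                              locality_span = 2, seed = 42)
  expect_identical(m1$syn_nn, m2$syn_nn)   # reproducible under seed
  expect_identical(m1$gap_mn, m2$gap_mn)

  m <- synthesize_connectome(map, locality_span = 1, seed = 1)
  # locality: every neuron-muscle synapse links cells <= 1 segment apart
  hits <- which(m$syn_nm, arr.ind = TRUE)
  dist <- abs(map$muscle_segment[hits[, 1]] -
                map$anchor_segment[hits[, 2]])
  expect_true(all(dist <= 1))

  # gap symmetry and empty diagonal survive construction
  expect_identical(m$gap_nn, t(m$gap_nn))
  expect_identical(m$gap_mm, t(m$gap_mm))
  expect_false(any(diag(m$gap_nn)))
  expect_false(any(diag(m$gap_mm)))

  # polarity-respecting chemical wiring: cholinergic -> D-class and
  # muscles; D-class -> cholinergic and muscles
  gaba <- map$neuron_class %in% c("DD", "VD")
  nn_hits <- which(m$syn_nn, arr.ind = TRUE)
  expect_true(all(xor(gaba[nn_hits[, 1]], gaba[nn_hits[, 2]])))

  # muscle->neuron synapses are exactly the proprioceptive pairs
  prop <- proprioceptive_wiring(map)
  expect_equal(sum(m$syn_mn), nrow(prop))
  expect_true(all(m$syn_mn[cbind(prop$neuron, prop$muscle)]))

  # command routing: forward lines to B classes, backward to A classes
  bcls <- map$neuron_class %in% c("DB", "VB")
  acls <- map$neuron_class %in% c("DA", "VA")
  expect_true(all(m$syn_in[bcls, 1:4]))
  expect_true(all(m$syn_in[acls, 5:10]))
  expect_false(any(m$syn_in[bcls, 5:10]))

  # nearest-neighbour gap chain along each muscle row
  for (rw in c("LD", "RD", "LV", "RV")) {
    idx <- row_indices(map, rw)
    expect_true(all(m$gap_mm[cbind(idx[-length(idx)], idx[-1])]))
  }
})

test_that("adjacency tables load into masks (wormwiring dialect)", {
  syn <- system.file("extdata", "synthetic_adjacency_syn.tsv",
                     package = "wormcpg")
  gap <- system.file("extdata", "synthetic_adjacency_gap.tsv",
                     package = "wormcpg")
  map <- neuron_index_map()
  expect_message(mask <- load_adjacency(syn, gap, map), "dropped")

  nm <- function(x) match(x, map$neuron_name)
  mus <- function(x) match(x, map$muscle_name)
  # count > 0 => TRUE (row = presynaptic)
  expect_true(mask$syn_nm[mus("MDL08"), nm("DA01")])
  expect_true(mask$syn_nm[mus("MDL08"), nm("DB01")])
  expect_true(mask$syn_nn[nm("DD01"), nm("DA01")])
  expect_true(mask$syn_in[nm("DB01"), 3])          # AVBL is command 3
  # count == 0 => FALSE
  expect_false(mask$syn_nm[mus("MVR01"), nm("DA01")])
  # muscle->neuron adjacency entry present alongside proprioceptive pairs
  expect_true(mask$syn_mn[nm("DA01"), mus("MDL08")])
  # gap entries symmetrized
  expect_true(mask$gap_nn[nm("DA01"), nm("DB01")])
  expect_true(mask$gap_nn[nm("DB01"), nm("DA01")])
  expect_true(mask$gap_mm[mus("MDL08"), mus("MDL09")])
  # cells outside the model are dropped, with a count
  expect_gt(attr(mask, "dropped_cells"), 0)

  # asymmetric gap counts: warning, then symmetrize
  g <- matrix(c(0, 2, 0, 0), 2, 2,
              dimnames = list(c("DA01", "DA02"), c("DA01", "DA02")))
  s <- matrix(0, 2, 2, dimnames = dimnames(g))
  expect_warning(m2 <- load_adjacency(s, g, map), "symmetriz")
  expect_true(m2$gap_nn[nm("DA01"), nm("DA02")] &&
                m2$gap_nn[nm("DA02"), nm("DA01")])

  # unresolvable garbage names are a hard error
  bad <- matrix(0, 1, 1, dimnames = list("not a cell!", "not a cell!"))
  expect_error(load_adjacency(bad, bad, map), "unresolvable")
})

test_that("mask serialization round-trips exactly", {
  mask <- tiny_mask(seed = 3, n_segments = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_connectome(mask, path)
  back <- read_connectome(path)
  for (nm in c("syn_nn", "syn_nm", "syn_mn", "syn_in",
               "gap_nn", "gap_mn", "gap_mm")) {
    expect_equal(unname(back[[nm]]), unname(mask[[nm]]), label = nm)
  }
  expect_equal(back$map$n_segments, mask$map$n_segments)
})
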