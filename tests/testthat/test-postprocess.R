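test_that("fill_holes fills enclosed cavities and nothing else", {
  # hollow 3x3 ring in one slice, sealed above and below -> solid block
  ring <- array(FALSE, c(3, 5, 5))
  ring[1:3, 2:4, 2:4] <- TRUE
  ring[2, 3, 3] <- FALSE
  filled <- fill_holes(ring)
  expect_true(filled[2, 3, 3])
  expect_equal(sum(filled), sum(ring) + 1)

  # solid mask unchanged; idempotence
  solid <- array(FALSE, c(4, 6, 6)); solid[2:3, 2:5, 2:5] <- TRUE
  expect_identical(fill_holes(solid), solid)
  expect_identical(fill_holes(filled), filled)

  # a notch open to the border is NOT filled
  open_notch <- solid
  open_notch[2, 2, 2] <- FALSE  # corner voxel, face-connected to outside
  expect_identical(fill_holes(open_notch), open_notch)

  # random masks: output ⊇ input and no enclosed background remains
  set.seed(31)
  for (i in 1:20) {
    m <- random_mask(c(7, 9, 9), n_balls = 3, r_range = c(1.5, 3))
    f <- fill_holes(m)
    expect_true(all(f[m]))
    expect_equal(sum(oracle_cavities(f)), 0)
    # exactly the oracle's cavities were added
    expect_identical(f, m | oracle_cavities(m))
  }
})

test_that("keep_largest_components retains the k largest, verified exhaustively", {
  m <- array(FALSE, c(3, 10, 10))
  m[1, 1:5, 1:2] <- TRUE           # size 10
  m[3, 9:10, 9] <- TRUE            # size 2
  k1 <- keep_largest_components(m, 1)
  expect_equal(sum(k1), 10)
  expect_true(all(k1[1, 1:5, 1:2]))

  # femoral-heads rule: two equal spheres, k = 2 keeps both
  two <- array(FALSE, c(5, 12, 12))
  two[2:3, 2:3, 2:3] <- TRUE
  two[2:3, 9:10, 9:10] <- TRUE
  expect_identical(keep_largest_components(two, 2), two)

  # random masks vs exhaustive component enumeration
  set.seed(32)
  for (i in 1:20) {
    m <- random_mask(c(6, 10, 10), n_balls = 4, r_range = c(0.9, 2))
    if (!any(m)) next
    k <- sample(1:3, 1)
    got <- keep_largest_components(m, k)
    lab <- oracle_components(m, 26)
    sizes <- tabulate(lab[lab > 0])
    keep <- order(-sizes, seq_along(sizes))[seq_len(min(k, length(sizes)))]
    expect_identical(got, array(lab %in% keep, dim(m)))
    expect_true(all(m[got]))   # output subset of input
    expect_lte(max(oracle_components(got, 26)), k)
  }

  # empty mask: warning, flagged empty
  e <- array(FALSE, c(3, 3, 3))
  expect_warning(r <- keep_largest_components(e, 1), "empty")
  expect_false(any(r))
})

test_that("morphological_smooth is a closing with a ball element", {
  solid <- array(FALSE, c(5, 9, 9)); solid[2:4, 3:7, 3:7] <- TRUE
  expect_identical(morphological_smooth(solid, 0), solid)
  expect_identical(morphological_smooth(solid, 1), solid)

  # a 1-voxel crack between two slabs is sealed by radius-1 closing,
  # cross-checked against dilation-then-erosion computed by loops
  notched <- array(FALSE, c(5, 9, 9))
  notched[2:4, 2:8, 3:4] <- TRUE
  notched[2:4, 2:8, 6:7] <- TRUE   # slabs either side of the x = 5 crack
  sm <- morphological_smooth(notched, 1)
  offs <- neighbor_offsets(6)  # radius-1 ball = center + 6 faces
  brute_dilate <- function(m) {
    out <- m
    for (i in which(m)) {
      ci <- arrayInd(i, dim(m))
      for (r in seq_len(nrow(offs))) {
        nb <- ci + offs[r, ]
        if (all(nb >= 1) && all(nb <= dim(m))) out[nb[1], nb[2], nb[3]] <- TRUE
      }
    }
    out
  }
  brute_erode <- function(m) {
    out <- m
    for (i in which(m)) {
      ci <- arrayInd(i, dim(m))
      for (r in seq_len(nrow(offs))) {
        nb <- ci + offs[r, ]
        # outside the (padded) grid counts as background
        if (any(nb < 1) || any(nb > dim(m)) || !m[nb[1], nb[2], nb[3]]) {
          out[ci[1], ci[2], ci[3]] <- FALSE
          break
        }
      }
    }
    out
  }
  pad1 <- function(m) {
    d <- dim(m)
    out <- array(FALSE, d + 2L)
    out[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- m
    out
  }
  want <- brute_erode(brute_dilate(pad1(notched)))[2:6, 2:10, 2:10]
  expect_identical(sm, want)
  expect_true(sm[3, 5, 5])  # crack interior sealed
})

test_that("fill and component retention compose idempotently", {
  set.seed(33)
  for (i in 1:5) {
    m <- random_mask(c(6, 10, 10), n_balls = 4)
    if (!any(m)) next
    once <- suppressWarnings(keep_largest_components(fill_holes(m), 2))
    twice <- suppressWarnings(keep_largest_components(fill_holes(once), 2))
    expect_identical(once, twice)
  }
})

test_that("corrupted phantom labels are exactly restored by post-processing", {
  cfg <- tiny_phantom_config(seed = 14, grid = c(10L, 40L, 40L))
  ph <- generate_phantom(cfg, "rt")
  clean <- ph$labels

  # component budgets matched to the true per-class component counts
  budgets <- sapply(1:4, function(cl) max(oracle_components(clean$data == cl)))
  rules <- postprocess_rules(keep_components = budgets)

  # holes go in the bladder (thick enough to host an enclosed cavity at
  # this grid); fragments go to classes whose smallest true component
  # exceeds a fragment's size, the premise of largest-component repair
  frag_classes <- which(sapply(1:4, function(cl) {
    comp <- oracle_components(clean$data == cl)
    min(tabulate(comp[comp > 0])) > 14
  }))
  cc_hole <- corruption_config(hole_count = 2, hole_radius_vox = 1,
                               classes = 1L, seed = 5)
  cc_frag <- corruption_config(fragment_count = 2, fragment_radius_vox = 1,
                               classes = frag_classes, seed = 15)
  corrupted <- corrupt_labels(corrupt_labels(clean, cc_hole), cc_frag)
  expect_false(identical(corrupted$data, clean$data))
  restored <- postprocess_labelmap(corrupted, rules)
  expect_identical(restored$data, clean$data)

  # clean labels are a fixed point (closing radius 0)
  expect_identical(postprocess_labelmap(clean, rules)$data, clean$data)

  # repair improves mean per-class DSC strictly
  d_bad <- mean(sapply(1:4, function(cl)
    dsc(corrupted$data == cl, clean$data == cl)))
  d_fix <- mean(sapply(1:4, function(cl)
    dsc(restored$data == cl, clean$data == cl)))
  expect_gt(d_fix, d_bad)
})

test_that("postprocess never increases per-class component counts", {
  set.seed(34)
  cfg <- tiny_phantom_config(seed = 15)
  ph <- generate_phantom(cfg, "pc")
  cc <- corruption_config(fragment_count = 3, seed = 6)
  corrupted <- corrupt_labels(ph$labels, cc)
  out <- postprocess_labelmap(corrupted, postprocess_rules())
  for (cl in 1:4) {
    before <- max(oracle_components(corrupted$data == cl))
    after <- max(oracle_components(out$data == cl))
    expect_lte(after, before)
  }
  # label codomain preserved
  expect_true(all(out$data %in% c(0L, sort(unique(c(corrupted$data))))))
})
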