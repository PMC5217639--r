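test_that("Ramachandran classification covers cores, outliers and edges", {
  expect_equal(rama_classify(-60, -45), "favored")   # alpha-helical core
  expect_equal(rama_classify(-120, 120), "favored")  # extended/beta
  expect_equal(rama_classify(0, 0), "outlier")
  # closed boundary: the corner of the beta favored rectangle counts
  expect_equal(rama_classify(-170, 90), "favored")
  # allowed margin outside the favored core
  expect_equal(rama_classify(-110, 0), "allowed")
  # angles wrap into (-180, 180]
  expect_equal(rama_classify(-60 + 360, -45 - 360), "favored")
  expect_true(is.na(rama_classify(NA, 10)))
})

test_that("region tables round trip through TSV and drive classification", {
  path <- system.file("extdata", "rama_regions.tsv", package = "cdk2substrate")
  regions <- read_rama_regions(path)
  expect_equal(regions, default_rama_regions(), ignore_attr = TRUE)
  strict <- regions[regions$region == "alphaR" & regions$class == "favored", ]
  expect_equal(rama_classify(-120, 120, strict), "outlier")
})

test_that("the Ramachandran filter separates clean from distorted models", {
  clean <- build_peptide(P27_PEPTIDE, c(-120, 120))
  distorted <- build_peptide(P27_PEPTIDE, c(40, -130)) # outside every region
  scores <- rama_filter(list(a = clean, b = distorted), threshold = 0.9)
  expect_equal(scores$frac_favored, c(1, 0))
  expect_equal(scores$passed_filter, c(TRUE, FALSE))
  # threshold 0 is vacuous
  expect_true(all(rama_filter(list(a = clean, b = distorted),
                              threshold = 0)$passed_filter))
  expect_error(rama_filter(list()), class = "cdk2substrate_validation_error")
  expect_error(rama_filter(list(clean), threshold = -1),
               class = "cdk2substrate_usage_error")
})

test_that("raising the threshold never lets more models through", {
  ens <- sample_ensemble(n_models = 30, jitter_sd = 25, seed = 9)
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 0.9, 1),
                   function(th) sum(rama_filter(ens, threshold = th)$passed_filter),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 30L)
})

test_that("model selection returns the minimum-RMSD model with stable ties", {
  ref <- reference_peptide()
  near <- build_peptide(P27_PEPTIDE, c(-121, 121), chain = "A", resno_start = 180L)
  far <- build_peptide(P27_PEPTIDE, c(-100, 100), chain = "A", resno_start = 180L)
  sel <- select_model(list(far = far, near = near, ref = ref), ref)
  expect_equal(sel$model_id, "ref")
  expect_equal(sel$rmsd, 0, tolerance = 1e-9)

  sel2 <- select_model(list(far = far, near = near), ref)
  expect_equal(sel2$model_id, "near")

  # ties break to the earliest model
  tie <- select_model(list(first = near, second = near), ref)
  expect_equal(tie$model_id, "first")

  # permutation changes nothing but the documented tie-break
  ens <- sample_ensemble(n_models = 12, jitter_sd = 12, seed = 4)
  a <- select_model(ens, ref)
  b <- select_model(rev(ens), ref)
  expect_equal(a$model_id, b$model_id)
  expect_equal(a$rmsd, b$rmsd, tolerance = 1e-12)
  expect_error(select_model(list(), ref),
               class = "cdk2substrate_validation_error")
})

test_that("hydrogen-bond detection honours both geometric criteria", {
  cplx <- suppressWarnings(
    make_complex_fixture(n_hbonds = 1, n_hbond_decoys = 2, n_salt_bridges = 0,
                         include_atp = FALSE, include_mg = 0,
                         restraint_satisfaction = c(p3_pt160 = FALSE,
                                                    p3_i270 = FALSE),
                         seed = 5)
  )
  man <- attr(cplx, "manifest")
  hb <- suppressWarnings(detect_hbonds(cplx, list(chain = "P"), list(chain = "A")))
  expect_equal(nrow(hb), 1L)
  expect_equal(hbond_key(hb), hbond_key(man$hbonds))
  expect_true(all(hb$distance < 3.5))
  expect_true(all(is.na(hb$angle) | hb$angle < 30))
  # the distance decoy sits at 3.8 and the angle decoy at 45 degrees;
  # neither may appear
  expect_false(any(paste(hb$acceptor_chain, hb$acceptor_resno) %in%
                     paste(man$decoys$acceptor_chain, man$decoys$acceptor_resno)))
})

test_that("detected contacts satisfy their inequalities on independent
           recomputation", {
  cplx <- suppressWarnings(make_complex_fixture(seed = 13))
  hb <- suppressWarnings(detect_hbonds(cplx, list(chain = "P"), list(chain = "A")))
  for (i in seq_len(nrow(hb))) {
    d <- select_atoms(cplx, chain = hb$donor_chain[i], resno = hb$donor_resno[i],
                      atom = hb$donor_atom[i])
    a <- select_atoms(cplx, chain = hb$acceptor_chain[i],
                      resno = hb$acceptor_resno[i], atom = hb$acceptor_atom[i])
    dist <- sqrt((d$x - a$x)^2 + (d$y - a$y)^2 + (d$z - a$z)^2)
    expect_equal(dist, hb$distance[i], tolerance = 1e-9)
    expect_lt(dist, 3.5)
  }
  sb <- detect_salt_bridges(cplx, list(chain = "P"), list(chain = "A"))
  expect_true(all(sb$distance <= 4.0))
})

test_that("salt-bridge detection applies the atom-class rule and cutoff", {
  # Lys NZ at 3.0 A from a Glu OE1 is a salt bridge; Ser OG is not basic
  st <- tibble::tibble(
    chain = c("P", "P", "A", "A"),
    resno = c(1L, 2L, 10L, 10L),
    resname = c("LYS", "SER", "GLU", "GLU"),
    atom = c("NZ", "OG", "OE1", "OE2"),
    element = c("N", "O", "O", "O"),
    x = c(0, 0, 3.0, 10), y = c(0, 5, 0, 5), z = 0,
    het = FALSE, serial = 1:4
  )
  sb <- detect_salt_bridges(st, list(chain = "P"), list(chain = "A"))
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$basic_atom, "NZ")
  # past the cutoff nothing is reported
  st$x[3] <- 4.5
  expect_equal(nrow(detect_salt_bridges(st, list(chain = "P"),
                                        list(chain = "A"))), 0L)
})

test_that("restraint checking flags satisfaction and flips on displacement", {
  cplx <- suppressWarnings(make_complex_fixture(seed = 3))
  man <- attr(cplx, "manifest")
  rep1 <- check_restraints(cplx, man$spec)
  expect_equal(stats::setNames(rep1$satisfied, rep1$name),
               man$restraint_expected)

  moved <- cplx
  is_p <- moved$chain == "P"
  moved$x[is_p] <- moved$x[is_p] + 10
  rep2 <- check_restraints(moved, man$spec)
  peptide_restraints <- c("p0_atp", "p3_pt160", "p3_i270")
  expect_false(any(rep2$satisfied[rep2$name %in% peptide_restraints]))

  # tightening max_distance can only shrink the satisfied set
  tighter <- man$spec
  tighter$max_distance <- tighter$max_distance / 2
  rep3 <- check_restraints(cplx, tighter)
  expect_true(all(which(rep3$satisfied) %in% which(rep1$satisfied)))

  bad <- restraint("missing", list(chain = "P", resno = 999),
                   list(chain = "A", resno = 160), 3.5)
  expect_error(check_restraints(cplx, bad), class = "cdk2substrate_spec_error")
})

test_that("unsatisfied restraint fixtures are reported as violated", {
  cplx <- suppressWarnings(make_complex_fixture(
    restraint_satisfaction = c(p0_atp = FALSE, p3_i270 = FALSE), seed = 8
  ))
  rep <- check_restraints(cplx, attr(cplx, "manifest")$spec)
  expect_false(rep$satisfied[rep$name == "p0_atp"])
  expect_false(rep$satisfied[rep$name == "p3_i270"])
  expect_true(rep$satisfied[rep$name == "p3_pt160"])
})

test_that("the interface report aggregates exactly the planted contacts", {
  cplx <- suppressWarnings(make_complex_fixture(
    n_hbonds = 3, n_hbond_decoys = 2, n_salt_bridges = 1,
    include_atp = FALSE, include_mg = 0,
    restraint_satisfaction = c(p3_pt160 = FALSE, p3_i270 = FALSE), seed = 21
  ))
  rep <- suppressWarnings(
    interface_report(cplx, list(c("P", "A"), c("P", "B")))
  )
  expect_equal(nrow(rep), 4L)
  expect_equal(sum(rep$type == "hbond"), 3L)
  expect_equal(sum(rep$type == "salt_bridge"), 1L)
  expect_true(all(grepl("^[A-Z][0-9]+-[A-Z][0-9]+$", rep$contact)))

  # stability across a PDB round trip
  path <- tempfile(fileext = ".pdb")
  write_pdb(cplx, path)
  rep2 <- suppressWarnings(
    interface_report(read_pdb(path), list(c("P", "A"), c("P", "B")))
  )
  expect_equal(rep2$contact, rep$contact)
  expect_equal(rep2$distance, rep$distance, tolerance = 0.005)

  expect_error(interface_report(cplx, list(c("P", "Z"))),
               class = "cdk2substrate_validation_error")
})

test_that("contact detection is invariant under a common rigid transform", {
  cplx <- suppressWarnings(make_complex_fixture(seed = 17))
  moved <- rigidly_transform(cplx)
  hb1 <- suppressWarnings(detect_hbonds(cplx, list(chain = "P"), list(chain = "A")))
  hb2 <- suppressWarnings(detect_hbonds(moved, list(chain = "P"), list(chain = "A")))
  expect_equal(hbond_key(hb2), hbond_key(hb1))
  expect_equal(sort(hb2$distance), sort(hb1$distance), tolerance = 1e-6)
  sb1 <- detect_salt_bridges(cplx, list(chain = "P"), list(chain = "A"))
  sb2 <- detect_salt_bridges(moved, list(chain = "P"), list(chain = "A"))
  expect_equal(salt_key(sb2), salt_key(sb1))
  r1 <- check_restraints(cplx, attr(cplx, "manifest")$spec)
  r2 <- check_restraints(moved, attr(cplx, "manifest")$spec)
  expect_equal(r2$min_distance, r1$min_distance, tolerance = 1e-6)
})

test_that("chains far apart yield an empty contact list", {
  cplx <- suppressWarnings(make_complex_fixture(
    n_hbonds = 0, n_hbond_decoys = 0, n_salt_bridges = 0,
    include_atp = FALSE, include_mg = 0,
    restraint_satisfaction = c(p3_pt160 = FALSE, p3_i270 = FALSE),
    peptide_offset = 20, seed = 6
  ))
  rep <- suppressWarnings(
    interface_report(cplx, list(c("P", "A"), c("P", "B")))
  )
  expect_equal(nrow(rep), 0L)
})
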