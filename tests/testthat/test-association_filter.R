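test_that("lead selection is strict at genome-wide significance", {
  gw <- rbind(make_gwas("Inflammatory bowel disease", "rs727088", 4.6e-9),
              make_gwas("Inflammatory bowel disease", "rs_edge", 5e-8),
              make_gwas("Crohn's disease", "rs_null", 0.3))
  leads <- significant_leads(gw)
  expect_equal(leads$`Inflammatory bowel disease`, "rs727088")
  expect_null(leads$`Crohn's disease`)
})

test_that("multiple studies of one disease merge at each rsid's minimum p", {
  gw <- rbind(make_gwas("Crohn's disease", "rs1", 1e-6),
              make_gwas("Crohn's disease", "rs1", 1e-9))
  leads <- significant_leads(gw)
  expect_equal(leads$`Crohn's disease`, "rs1")
  lead_tab <- attach_associations(
    make_candidates("rs1", "hsa-miR-1", "G1"),
    rbind(gw, make_gwas("Ulcerative colitis", "rs1", 1e-10)),
    make_ld(character(), character(), numeric(), numeric()))
  expect_equal(lead_tab$p_value[lead_tab$disease == "Crohn's disease"], 1e-9)
})

test_that("proxy lookup enforces r2 >= 0.8 and D' = 1", {
  ld <- rbind(make_ld("leadX", "rs60474474", 1, 1),
              make_ld("leadX", "rs_low", 0.79, 1),
              make_ld("leadX", "rs_dp", 0.9, 0.98),
              make_ld("rs_rev", "leadX", 0.85, 1))
  expect_setequal(ld_proxies("leadX", ld),
                  c("leadX", "rs60474474", "rs_rev"))
  # the query is always its own proxy, even with no pairs at all
  expect_equal(ld_proxies("rs_alone", ld), "rs_alone")
  # D' requirement can be configured off
  cfg <- mirsnp_config(ld_dprime_required = NA)
  expect_true("rs_dp" %in% ld_proxies("leadX", ld, cfg))
})

test_that("direct evidence is preferred and carries the merged statistics", {
  cand <- make_candidates(c("rs2070197", "rs_proxy", "rs_none"),
                          sprintf("hsa-miR-%d", 1:3),
                          c("IRF5", "PTPN2", "G3"))
  gw <- rbind(make_gwas("Systemic lupus erythematosus", "rs2070197", 3.0e-40,
                        lead = TRUE),
              make_gwas("Crohn's disease", "rs_lead", 2.2e-12),
              make_gwas("Crohn's disease", "rs2070197", 1e-9))
  ld <- rbind(make_ld("rs_lead", "rs_proxy", 1, 1),
              make_ld("rs_lead", "rs2070197", 1, 1))
  out <- attach_associations(cand, gw, ld)

  sle <- out[out$disease == "Systemic lupus erythematosus", ]
  expect_equal(sle$rsid, "rs2070197")
  expect_equal(sle$support, "direct")
  expect_equal(sle$p_value, 3.0e-40)
  expect_true(sle$is_reported_lead)

  cd <- out[out$disease == "Crohn's disease", ]
  # rs2070197 is both a lead and a proxy for CD: direct wins
  expect_equal(cd$support[cd$rsid == "rs2070197"], "direct")
  prox <- cd[cd$rsid == "rs_proxy", ]
  expect_equal(prox$support, "ld_proxy")
  expect_equal(prox$proxy_lead_rsid, "rs_lead")
  expect_true(is.na(prox$p_value))  # own statistics stay missing
  expect_false("rs_none" %in% out$rsid)
})

test_that("best proxy is highest r2 with lexicographic tie-break", {
  cand <- make_candidates("rs_p", "hsa-miR-1", "G1")
  gw <- rbind(make_gwas("Crohn's disease", "rs_leadB", 1e-9),
              make_gwas("Crohn's disease", "rs_leadA", 1e-10),
              make_gwas("Crohn's disease", "rs_leadC", 1e-12))
  ld <- rbind(make_ld("rs_leadB", "rs_p", 0.9, 1),
              make_ld("rs_leadA", "rs_p", 0.95, 1),
              make_ld("rs_leadC", "rs_p", 0.95, 1))
  out <- attach_associations(cand, gw, ld)
  expect_equal(out$proxy_lead_rsid, "rs_leadA")  # ties resolve to A < C
  expect_equal(out$proxy_r2, 0.95)
})

test_that("association filter agrees with the brute-force double loop", {
  set.seed(19)
  for (rep in 1:5) {
    n_snp <- 50
    rsids <- sprintf("rs%03d", sample(999, n_snp))
    diseases <- sample(aid_diseases(), 4)
    gw <- data.frame(
      disease = sample(diseases, 120, replace = TRUE),
      rsid = sample(rsids, 120, replace = TRUE),
      p_value = 10^runif(120, -12, 0),
      odds_ratio = 1.1, is_reported_lead = FALSE,
      stringsAsFactors = FALSE)
    ld <- data.frame(
      rsid_a = sample(rsids, 80, replace = TRUE),
      rsid_b = sample(rsids, 80, replace = TRUE),
      r2 = round(runif(80, 0.5, 1), 2),
      dprime = sample(c(1, 1, 0.97), 80, replace = TRUE),
      stringsAsFactors = FALSE)
    ld <- ld[ld$rsid_a != ld$rsid_b, ]
    cand <- make_candidates(rsids[1:20], sprintf("hsa-miR-%d", 1:20),
                            sprintf("G%d", 1:20))
    cfg <- mirsnp_config()
    got <- attach_associations(cand, gw, ld, cfg)
    got <- got[order(got$rsid, got$disease),
               c("rsid", "disease", "support", "proxy_lead_rsid",
                 "proxy_r2")]
    rownames(got) <- NULL
    want <- oracle_attach(unique(cand$rsid), gw, ld, cfg)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("the shared-disease rule counts distinct labels", {
  assoc <- data.frame(
    rsid = c("rs1", "rs2", "rs2", "rs3", "rs3", "rs3"),
    disease = c("Crohn's disease", "Crohn's disease", "Type 1 diabetes mellitus",
                "Inflammatory bowel disease", "Crohn's disease",
                "Ulcerative colitis"),
    p_value = NA_real_, odds_ratio = NA_real_, is_reported_lead = FALSE,
    support = "ld_proxy", proxy_lead_rsid = "rs_l", proxy_r2 = 1,
    proxy_dprime = 1, stringsAsFactors = FALSE)
  out <- shared_disease_filter(assoc)
  expect_false("rs1" %in% out$rsid)              # one disease only
  expect_true("rs2" %in% out$rsid)               # two diseases
  expect_equal(sum(out$rsid == "rs3"), 3L)       # IBD/CD/UC count as three
  # duplicated evidence for the same disease does not inflate the count
  dup <- assoc[assoc$rsid == "rs1", ][c(1, 1), ]
  expect_equal(nrow(shared_disease_filter(dup)), 0L)
})

test_that("filtering is monotone in the thresholds", {
  set.seed(23)
  rsids <- sprintf("rs%02d", 1:30)
  gw <- data.frame(disease = sample(aid_diseases()[1:3], 60, replace = TRUE),
                   rsid = sample(rsids, 60, replace = TRUE),
                   p_value = 10^runif(60, -10, 0), odds_ratio = 1,
                   is_reported_lead = FALSE, stringsAsFactors = FALSE)
  ld <- data.frame(rsid_a = sample(rsids, 40, replace = TRUE),
                   rsid_b = sample(rsids, 40, replace = TRUE),
                   r2 = runif(40, 0.5, 1), dprime = 1,
                   stringsAsFactors = FALSE)
  cand <- make_candidates(rsids[1:15], sprintf("hsa-miR-%d", 1:15),
                          sprintf("G%d", 1:15))
  strict <- attach_associations(cand, gw, ld, mirsnp_config())
  relaxed_p <- attach_associations(cand, gw, ld,
                                   mirsnp_config(gwas_p_threshold = 1e-4))
  relaxed_r2 <- attach_associations(cand, gw, ld,
                                    mirsnp_config(ld_r2_min = 0.5))
  key <- function(x) paste(x$rsid, x$disease)
  expect_true(all(key(strict) %in% key(relaxed_p)))
  expect_true(all(key(strict) %in% key(relaxed_r2)))
})
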