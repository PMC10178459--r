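# Hand-worked decision-tree fixture suite. Each fixture pins the expected
# classification and the rule that fires, for one model on one table.
# Percent layouts are exact (counts = pct/100 * total with integral results).

decision_fixtures <- function() {
  set.seed(1203)
  fx <- list()
  add <- function(name, model, call, rule, pcts, total, target = "TRG") {
    fx[[name]] <<- list(
      name = name, model = model, call = call, rule = rule,
      tbl = pct_tbl(pcts, total, target = target, sample_id = name)
    )
  }
  bg <- function(x, k = 8) rep(x, k)

  # ---- Roswell Park, B-cell tree (steps 1-7) ----
  add("rp_b_step1_invalid", "roswell_park", "INVALID", "step1",
      c(10, 5, bg(0.5)), 10000, "IGH_FR1")
  add("rp_b_step2_clonal", "roswell_park", "CLONAL", "step2",
      c(20, 15, bg(0.5)), 100000, "IGH_FR1")
  add("rp_b_step3_nec", "roswell_park", "NEC", "step3",
      c(10, 5, bg(2)), 100000, "IGH_FR1")          # no clone <= 1% in ranks 3-10
  add("rp_b_step4_nec", "roswell_park", "NEC", "step4",
      c(2, 1, bg(0.5)), 100000, "IGH_FR2")         # top2 3 < 10 x 0.5
  add("rp_b_step7_clonal", "roswell_park", "CLONAL", "step7",
      c(2, 1, bg(0.2)), 50000, "IGH_FR1")          # top2 3 >= 2.5, >= 10 x 0.2
  add("rp_b_step7_nec", "roswell_park", "NEC", "step7",
      c(1.2, 0.8, bg(0.1)), 100000, "IGH_FR3")     # top2 2 < 2.5
  add("rp_b_step6_clonal_igk", "roswell_park", "CLONAL", "step6",
      c(4, 2, bg(0.3)), 100000, "IGK")             # top2 6 >= 5
  add("rp_b_step6_nec_igk", "roswell_park", "NEC", "step6",
      c(3, 1, bg(0.2)), 50000, "IGK")              # top2 4 < 5
  # the IGK background ceiling is 1.25, the FR ceiling 1.0: same layout flips
  add("rp_b_igk_ceiling_clonal", "roswell_park", "CLONAL", "step6",
      c(10, 5, bg(1.2)), 100000, "IGK")            # 1.2 <= 1.25 qualifies
  add("rp_b_fr_ceiling_nec", "roswell_park", "NEC", "step3",
      c(10, 5, bg(1.2)), 100000, "IGH_FR1")        # 1.2 > 1 does not

  # ---- Roswell Park, T-cell tree (steps 1-5) ----
  add("rp_t_step1_invalid", "roswell_park", "INVALID", "step1",
      c(60, 10, bg(0.5)), 10000)
  add("rp_t_step2_clonal", "roswell_park", "CLONAL", "step2",
      c(45, 10, bg(0.3)), 100000)                  # top2 55 >= 50
  add("rp_t_step3_nec_restricted", "roswell_park", "NEC", "step3",
      c(30, 10, bg(2)), 100000)                    # restricted repertoire
  add("rp_t_step4_nec", "roswell_park", "NEC", "step4",
      c(3, 1, bg(0.5)), 100000)                    # top2 4 < 10 x 0.5
  add("rp_t_step5_clonal", "roswell_park", "CLONAL", "step5",
      c(30, 10, bg(0.3)), 100000)                  # top2 40 in [5, 50)
  add("rp_t_step5_nec", "roswell_park", "NEC", "step5",
      c(4, 0.8, bg(0.3)), 50000)                   # top2 4.8 < 5

  # ---- Invivoscribe ----
  add("iv_invalid", "invivoscribe", "INVALID", "read_gate",
      c(30, 1, bg(0.9)), 15000)
  add("iv_clonal", "invivoscribe", "CLONAL", "dominant_clone",
      c(30, 1, bg(0.9)), 100000)                   # 30 >= 2.5 and >= 10 x 0.9
  add("iv_clonal_boundary", "invivoscribe", "CLONAL", "dominant_clone",
      c(2.5, 0.5, 0.25, bg(0.1, 5)), 40000)        # inclusive 2.5% / 10x
  add("iv_nec_pct", "invivoscribe", "NEC", "no_dominant_clone",
      c(2.4, 0.1, bg(0.1)), 50000)                 # fails the 2.5% gate
  add("iv_nec_ratio", "invivoscribe", "NEC", "no_dominant_clone",
      c(5, 4, 3.8, bg(0.5, 5)), 50000)             # 5 < 10 x 3.8

  # ---- MSK / Arcila ----
  add("msk_invalid", "msk", "INVALID", "read_gate",
      c(30, 1, bg(0.5)), 29000)
  add("msk_clonal_high", "msk", "CLONAL", "dominant_high_reads",
      c(20, 0.5, bg(0.4)), 120000)                 # 2.5% / 10x branch
  add("msk_nec_low", "msk", "NEC", "no_dominant_low_reads",
      c(4.9, 0.2, bg(0.1)), 50000)                 # 5% gate in 30k-100k branch
  add("msk_clonal_low", "msk", "CLONAL", "dominant_low_reads",
      c(10, 0.3, bg(0.2)), 50000)                  # 10 >= 5 and >= 20 x 0.2
  add("msk_oligoclonal", "msk", "OLIGOCLONAL", "oligoclonal_high_reads",
      c(10, 9, 8, bg(0.3, 7)), 200000)             # 3 dominant, > 100k reads

  # ---- Nollet/Schumaker and the modified read gate ----
  add("ns_invalid", "nollet_schumaker", "INVALID", "read_gate",
      c(40, 5, bg(1)), 800)
  add("nsmod_invalid", "ns_modified", "INVALID", "read_gate",
      c(40, 5, bg(1)), 15000)
  add("ns_clonal", "nollet_schumaker", "CLONAL", "dominant_clone",
      c(40, 5, bg(1)), 30000)                      # bkg 5; 40 >= 4, >= 22.5
  add("ns_nec_polyclonal", "nollet_schumaker", "NEC", "polyclonal",
      c(1.8, 1.7, bg(1.5)), 30000)                 # no clone above 2%
  add("ns_minor_with_bkg", "nollet_schumaker", "POLYCLONAL_MINOR",
      "minor_clonal_rearrangements",
      c(3.5, 1, bg(0.8)), 40000)                   # 3.5 < 4, but 3.5 > 2
  add("ns_minor_undef_bkg", "nollet_schumaker", "POLYCLONAL_MINOR",
      "minor_clonal_rearrangements",
      c(3.9, 3.5, 3.2, 3, 2.8, 2.6, 2.5, 2.4, 2.3, 2.2), 100000)
  add("nsmod_clonal", "ns_modified", "CLONAL", "dominant_clone",
      c(40, 5, bg(1)), 30000)

  fx
}
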