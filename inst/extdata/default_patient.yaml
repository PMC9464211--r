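# Reference parameter registry of the virtual dialysis patient.
# Every key can be overridden; unknown keys are rejected at load time.
# provenance per key:
#   [source]  value printed in the source study for this model
#   [default] self-defined physiological default of this package
#             (circulation, baroreflex, transport and dialyzer-side values;
#              see the methods vignette for the rationale)
patient:
  weight_kg: 70  # [source]
  overload_mL: 3000  # [source]
  V_ic_n: 22000  # [default]
  k_cellwater: 6.5999999999999996  # [default]
  fpl_slope: 0.01  # [default]
  w_v: 0.80000000000000004  # [source]
  P_sv_n: 12  # [source]
  donnan.z_alb: -17  # [default]
  donnan.z_glob: -6  # [default]
  donnan.mw_alb: 66.400000000000006  # [default]
  donnan.mw_glob: 170  # [default]
  circ.BV_n: 5000  # [default]
  circ.CO_n: 6500  # [default]
  circ.Hct0: 0.40000000000000002  # [default]
  circ.frac.large_arteries: 0.10000000000000001  # [default]
  circ.frac.small_arteries: 0.050000000000000003  # [default]
  circ.frac.capillaries: 0.050000000000000003  # [default]
  circ.frac.small_veins: 0.46999999999999997  # [default]
  circ.frac.large_veins: 0.14999999999999999  # [default]
  circ.frac.right_heart: 0.029999999999999999  # [default]
  circ.frac.pulm_arteries: 0.025999999999999999  # [default]
  circ.frac.pulm_veins: 0.089999999999999997  # [default]
  circ.frac.left_heart: 0.034000000000000002  # [default]
  circ.P_n.large_arteries: 93  # [default]
  circ.P_n.small_arteries: 75  # [default]
  circ.P_n.capillaries: 18  # [default]
  circ.P_n.small_veins: 12  # [default]
  circ.P_n.large_veins: 5  # [default]
  circ.P_n.right_heart: 4  # [default]
  circ.P_n.pulm_arteries: 15  # [default]
  circ.P_n.pulm_veins: 8  # [default]
  circ.P_n.left_heart: 5  # [default]
  circ.C.large_arteries: 1.2  # [default]
  circ.C.small_arteries: 0.80000000000000004  # [default]
  circ.C.capillaries: 3  # [default]
  circ.C.small_veins: 100  # [default]
  circ.C.large_veins: 60  # [default]
  circ.C.right_heart: 20  # [default]
  circ.C.pulm_arteries: 4  # [default]
  circ.C.pulm_veins: 25  # [default]
  circ.C.left_heart: 15  # [default]
  baro.gain.hr: 0.02  # [default]
  baro.gain.ctr: 0.014999999999999999  # [default]
  baro.gain.res: 0.029999999999999999  # [default]
  baro.gain.vu: 100  # [default]
  baro.amp.hr: 0.29999999999999999  # [default]
  baro.amp.ctr: 0.29999999999999999  # [default]
  baro.amp.res: 0.5  # [default]
  baro.amp.vu: 500  # [default]
  baro.tau.hr: 0.5  # [default]
  baro.tau.ctr: 1  # [default]
  baro.tau.res: 1  # [default]
  baro.tau.vu: 2  # [default]
  pores.radii.large: 250  # [source]
  pores.radii.small: 45  # [source]
  pores.radii.ultrasmall: 2  # [source]
  pores.alpha.large: 0.050000000000000003  # [source]
  pores.alpha.small: 0.84999999999999998  # [source]
  pores.alpha.ultrasmall: 0.10000000000000001  # [source]
  pores.LpS: 6  # [source]
  pores.RT: 19.300000000000001  # [source]
  interstitium.P_is_n: -1  # [source]
  interstitium.V_is_n: 15000  # [source]
  interstitium.C_is: 1800  # [source]
  interstitium.Q_L_n: 5.5555555555555554  # [source]
  interstitium.LS: 0.71833333333333338  # [source]
  interstitium.V_is_ex: 7500  # [source]
  solutes.valence.Na: 1  # [default]
  solutes.valence.K: 1  # [default]
  solutes.valence.Cl: -1  # [default]
  solutes.valence.HCO3: -1  # [default]
  solutes.valence.urea: 0  # [default]
  solutes.valence.creatinine: 0  # [default]
  solutes.valence.other_anions: -2  # [default]
  solutes.phi.Na: 0.93000000000000005  # [default]
  solutes.phi.K: 0.93000000000000005  # [default]
  solutes.phi.Cl: 0.93000000000000005  # [default]
  solutes.phi.HCO3: 0.93000000000000005  # [default]
  solutes.phi.urea: 1  # [default]
  solutes.phi.creatinine: 1  # [default]
  solutes.phi.other_anions: 1  # [default]
  solutes.radius.Na: 2.2999999999999998  # [default]
  solutes.radius.K: 2  # [default]
  solutes.radius.Cl: 1.8  # [default]
  solutes.radius.HCO3: 2.1000000000000001  # [default]
  solutes.radius.urea: 2.6000000000000001  # [default]
  solutes.radius.creatinine: 3  # [default]
  solutes.radius.other_anions: 2.7999999999999998  # [default]
  solutes.PS_cap.Na: 6000  # [default]
  solutes.PS_cap.K: 6000  # [default]
  solutes.PS_cap.Cl: 7000  # [default]
  solutes.PS_cap.HCO3: 6000  # [default]
  solutes.PS_cap.urea: 8000  # [default]
  solutes.PS_cap.creatinine: 3000  # [default]
  solutes.PS_cap.other_anions: 0  # [default]
  solutes.CL.Na: 200  # [default]
  solutes.CL.K: 200  # [default]
  solutes.CL.Cl: 200  # [default]
  solutes.CL.HCO3: 100  # [default]
  solutes.CL.urea: 200  # [default]
  solutes.CL.creatinine: 180  # [default]
  solutes.CL.other_anions: 25  # [default]
  solutes.c_di.Na: 140  # [default]
  solutes.c_di.K: 2  # [default]
  solutes.c_di.Cl: 111  # [default]
  solutes.c_di.HCO3: 32  # [default]
  solutes.c_di.urea: 0  # [default]
  solutes.c_di.creatinine: 0  # [default]
  solutes.c_di.other_anions: 0  # [default]
  solutes.alphaD.Na: 0.94999999999999996  # [default]
  solutes.alphaD.K: 0.94999999999999996  # [default]
  solutes.alphaD.Cl: 1.05  # [default]
  solutes.alphaD.HCO3: 1.05  # [default]
  solutes.alphaD.urea: 1  # [default]
  solutes.alphaD.creatinine: 1  # [default]
  solutes.alphaD.other_anions: 1.05  # [default]
  solutes.c_pl0.Na: 138  # [default]
  solutes.c_pl0.K: 5  # [default]
  solutes.c_pl0.Cl: 102  # [default]
  solutes.c_pl0.HCO3: 22  # [default]
  solutes.c_pl0.urea: 20  # [default]
  solutes.c_pl0.creatinine: 0.80000000000000004  # [default]
  solutes.c_ic0.Na: 12  # [default]
  solutes.c_ic0.K: 140  # [default]
  solutes.c_ic0.Cl: 4  # [default]
  solutes.c_ic0.HCO3: 10  # [default]
  solutes.c_ic0.other_anions: 100  # [default]
  solutes.PS_cell.Na: 100  # [default]
  solutes.PS_cell.K: 800  # [default]
  solutes.PS_cell.Cl: 0  # [default]
  solutes.PS_cell.HCO3: 0  # [default]
  solutes.PS_cell.urea: 700  # [default]
  solutes.PS_cell.creatinine: 500  # [default]
  solutes.PS_cell.other_anions: 50  # [default]
  solutes.cell_stiff.Na: 1  # [default]
  solutes.cell_stiff.K: 0.5  # [default]
  solutes.cell_stiff.Cl: 1  # [default]
  solutes.cell_stiff.HCO3: 1  # [default]
  solutes.cell_stiff.urea: 1  # [default]
  solutes.cell_stiff.creatinine: 1  # [default]
  solutes.cell_stiff.other_anions: 0.5  # [default]
  solutes.sigma_cell.Na: 1  # [default]
  solutes.sigma_cell.K: 1  # [default]
  solutes.sigma_cell.Cl: 1  # [default]
  solutes.sigma_cell.HCO3: 1  # [default]
  solutes.sigma_cell.urea: 0.050000000000000003  # [default]
  solutes.sigma_cell.creatinine: 0.5  # [default]
  solutes.sigma_cell.other_anions: 1  # [default]
  proteins.radius.albumin: 35.5  # [default]
  proteins.radius.globulin: 52  # [default]
  proteins.PS_large.albumin: 2  # [default]
  proteins.PS_large.globulin: 1.5  # [default]
  proteins.PS_small.albumin: 0.5  # [default]
  proteins.PS_small.globulin: 0.050000000000000003  # [default]
  proteins.TP0: 7  # [default]
  proteins.a_pl0: 0.59999999999999998  # [default]
protocol:
  duration_min: 240      # [source] standard 4-h session
  uf_total_mL: 3000      # [source] 3 L net ultrafiltration
  priming: discarded     # [source] basal priming procedure
  circuit_mL: 220        # [source] 100 mL dialyzer + 120 mL tubing
  Qb: 300                # [default] dialyzer blood flow (implicit in clearances)
  saline_Na: 154         # [default] 0.9% saline
  saline_Cl: 154         # [default]
  dialyzer: yes          # [default] diffusive dialyzer exchange active
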