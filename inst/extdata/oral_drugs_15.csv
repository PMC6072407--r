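# Input data for 15 marketed oral drugs: charge type, pKa, aqueous solubility
# at pH 7.4 (M, room temperature), apparent Caco-2 permeability A->B at pH 6.5
# (cm/s), human Vss (L/kg), human plasma clearance (mL/min/kg) and plasma
# protein binding (% bound; blank where unavailable).
# Molecular weights (g/mol) are standard free-acid/free-base monograph values
# (drug monographs / PubChem), required to convert molar solubility to mass.
name,charge_type,pka,solubility_ph74,papp_caco2_ph65,vss_per_kg,cl_per_kg,ppb_percent_bound,mol_weight
chlorpromazine,monobase,9.24,3.72e-4,2.00e-5,10.00,16.00,98.64,318.86
diazepam,neutral,,1.57e-4,6.03e-5,1.00,0.38,98.61,284.74
diclofenac,monoacid,4.26,6.53e-3,5.37e-5,0.19,3.83,99.68,296.15
furosemide,monoacid,3.94,1.78e-1,2.82e-7,0.11,2.19,98.37,330.74
haloperidol,monobase,8.63,7.56e-5,1.58e-5,17.00,7.80,85.48,375.86
imipramine,monobase,9.50,9.85e-3,2.75e-5,12.00,13.00,87.87,280.41
indomethacin,monoacid,4.31,1.44e-3,2.95e-5,0.16,1.61,,357.79
ketoprofen,monoacid,4.25,5.55e-1,4.68e-5,0.13,1.60,98.73,254.28
naproxen,monoacid,4.23,9.87e-2,4.68e-5,0.09,0.07,,230.26
nifedipine,neutral,,5.23e-5,3.24e-5,0.79,7.30,96.17,346.33
phenytoin,monoacid,8.06,8.51e-5,3.98e-5,1.40,0.57,87.11,252.27
pindolol,monobase,9.54,2.62e-2,3.89e-5,1.20,7.70,,248.32
prazosin,monobase,6.50,1.48e-5,4.07e-6,0.73,4.70,96.00,383.40
trimethoprim,monobase,7.26,2.17e-3,8.71e-5,1.50,2.10,66.10,290.32
warfarin,monoacid,4.97,3.35e-3,4.37e-5,0.12,0.05,99.31,308.33
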