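# Bundled cross-linker catalog (monoisotopic Da, spacer arm in Angstrom).
# Representative subset spanning MS-cleavable/non-cleavable, symmetric
# reagents and zero-length chemistry; per-linker residue specificity
# follows vendor literature (NHS esters: K + protein N-terminus; EDC:
# carboxyl-to-amine condensation; sulfo-SDA: NHS x photo-diazirine,
# modelled as a mass entry only).
# DSSO cleaves at its C-S bonds into the alkene (54.010565) / sulfenic acid
# (103.993200) remnant pair. An alternative thiol channel
# (85.982635:72.021129, thiol vs alkene with retained water) also satisfies
# remnant conservation and can be enabled by appending it to remnant_pairs
# in a user catalog.
name,site_a,site_b,nterm_reactive,spacer_arm_A,cleavable,intact_delta,remnant_pairs
DSSO,K,K,TRUE,10.3,TRUE,158.003765,54.010565:103.993200
DSBU,K,K,TRUE,12.5,TRUE,196.084792,85.052764:111.032028
DSS,K,K,TRUE,11.4,FALSE,138.068080,
BS3,K,K,TRUE,11.4,FALSE,138.068080,
sulfo-SDA,K,GASPVTCLINDQKEMHFRYW,TRUE,3.9,FALSE,82.041865,
EDC,DE,K,TRUE,0.0,FALSE,-18.010565,
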