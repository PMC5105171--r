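# Synthetic stand-in per-PFT respiration parameters (E0 in K, k dimensionless).
# These are NOT site-calibrated values; see ?default_pft_params.
pft,E0,k
tropical_forest,100,0.50
savanna,120,0.40
grassland,150,0.35
temperate_forest,200,0.30
boreal_forest,300,0.15
tundra,350,0.10
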