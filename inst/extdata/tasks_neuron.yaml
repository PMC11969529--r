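- id: atp_from_glc_o2
  description: regenerate ATP from glucose and oxygen
  inputs:
    glc[e]: 1.0
    o2[e]: 10.0
  outputs:
    co2[c]: 0.0
    lac[c]: 0.0
  bounds:
    ATPM:
    - 2.0
    - 1000.0
- id: biomass_precursors
  description: grow on glucose, oxygen and ammonia
  inputs:
    glc[e]: 1.0
    o2[e]: 10.0
    nh4[e]: 1.0
  outputs:
    biomass[c]: 0.05
    co2[c]: 0.0
    lac[c]: 0.0
- id: gln_to_glu
  description: produce glutamate from glutamine
  inputs:
    gln[e]: 1.0
  outputs:
    glu[c]: 0.5
    nh4[c]: 0.0
- id: glu_to_gaba
  description: convert glutamate into GABA
  inputs:
    glu[e]: 1.0
  outputs:
    gaba[c]: 0.5
    co2[c]: 0.0
- id: gaba_to_glu
  description: convert GABA into glutamate
  inputs:
    gaba[e]: 1.0
    glc[e]: 1.0
    o2[e]: 10.0
  outputs:
    glu[c]: 0.5
    co2[c]: 0.0
    lac[c]: 0.0
- id: ser_to_gly
  description: convert serine into glycine
  inputs:
    ser[e]: 1.0
  outputs:
    gly[c]: 0.5
- id: bcaa_transamination
  description: transaminate leucine, isoleucine and valine to their keto-acids
  inputs:
    leu[e]: 1.0
    ile[e]: 1.0
    val[e]: 1.0
    glc[e]: 2.0
    o2[e]: 10.0
    nh4[e]: 1.0
  outputs:
    kic[c]: 0.2
    kmv[c]: 0.2
    kiv[c]: 0.2
    glu[c]: 0.0
    co2[c]: 0.0
    lac[c]: 0.0
- id: ldopa_to_dopamine
  description: produce dopamine from levodopa
  inputs:
    ldopa[e]: 1.0
  outputs:
    dopa[c]: 0.5
    co2[c]: 0.0
- id: dopamine_to_ne
  description: convert dopamine into norepinephrine
  inputs:
    dopa[e]: 1.0
    o2[e]: 10.0
  outputs:
    ne[c]: 0.5
- id: adrenaline_production
  description: produce adrenaline from levodopa
  inputs:
    ldopa[e]: 1.0
    o2[e]: 10.0
  outputs:
    adr[c]: 0.5
    co2[c]: 0.0
- id: acetylcholine_production
  description: produce acetylcholine
  inputs:
    glc[e]: 1.0
    o2[e]: 10.0
    chln[e]: 1.0
  outputs:
    ach[c]: 0.1
    co2[c]: 0.0
    lac[c]: 0.0
- id: naa_synthesis
  description: synthesize NAA from glucose-derived precursors
  inputs:
    glc[e]: 1.0
    o2[e]: 10.0
    nh4[e]: 1.0
  outputs:
    naa[c]: 0.1
    co2[c]: 0.0
    lac[c]: 0.0
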