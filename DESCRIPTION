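Package: fontanlpm
Title: Lumped-Parameter Hemodynamic Modelling of the Fontan Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale (0D) hemodynamic analysis of a fenestrated
    lateral-tunnel Fontan circulation. Provides a calibrated open-loop
    lumped-parameter model of the single-ventricle circulation (two-Hill
    time-varying elastance chamber, dynamically controlled valves,
    three-element Windkessel vascular beds, and a reduced-order surrogate
    of the Fontan pathway with fenestration), a virtual endovascular
    revision operator that swaps the dilated pathway for a bifurcated
    endograft, face-flux energy dissipation and efficiency analysis,
    derivative-free calibration of model parameters against clinical flow
    and pressure summaries, and a synthetic clinical-data generator
    emulating cardiac-gated PC-MRI flow and catheter pressure
    acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
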