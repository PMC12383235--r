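Package: abmorph
Title: Morphometry, Kinetics and Channel Biophysics of Amyloid-beta
    Prefibrillar Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of amyloid-beta (Abeta42) prefibrillar
    assemblies: tracing and morphometry of oligomers, curvilinear
    protofibrils and annular (ring) assemblies in AFM height maps and
    EM-style density fields; cross-sectional diameters measured at a
    configurable threshold above baseline; assembly kinetics (thioflavin-T
    lag-phase timing and real-time bidirectional elongation rates);
    single-channel patch-clamp idealization and windowed modal
    conductance; the Hille access-resistance mapping between channel
    conductance and pore diameter; and stoichiometry conversions between
    geometry, mass and monomer counts.  Includes synthetic-data
    generators with known ground truth for every input modality, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    signal,
    igraph,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
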