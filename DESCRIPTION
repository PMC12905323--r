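Package: icuplan
Title: Reinforcement-Learning Planning of Shadow-Free Intercostal Ultrasound Scanning Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual-environment toolkit for planning ultrasound scanning
    trajectories through intercostal spaces. Provides synthetic thoracic
    phantoms with configurable rib geometry and ingestion of segmented
    anatomy (STL/PLY meshes, NIfTI label maps); a cylindrical-coordinate
    probe model with skin-surface projection; a voxelized Markov decision
    process with ray-cast bone shadows and a decomposed reward balancing
    target coverage, acoustic attenuation and shadow avoidance; a dueling
    double deep Q-network with prioritized experience replay trained on the
    simulator; and evaluation protocols (success rate, step counts,
    shadow/attenuation summaries, target-position heatmaps, multi-target
    episodes).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
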