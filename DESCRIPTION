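Package: simplexstent
Title: Virtual Balloon-Expandable Stent Deployment on 2-Simplex Meshes
Version: 0.1.0
Authors@R: person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Rapid virtual deployment of balloon-expandable coronary stents in
    triangulated 3D vessel geometries using a 2-simplex deformable surface
    model. Converts a luminal triangulation to its dual polygonal (2-simplex)
    mesh, generates a crimped stent mesh by inward projection along the vessel
    centerline, expands it with a mechanics-informed internal force derived
    from device parameters (radial rigidity, nominal radial force), resists
    expansion with a contact-activated external force based on a reduced
    polynomial hyperelastic artery wall, and quantifies lumen agreement with
    frame-wise mean lumen diameter profiles, Bland-Altman statistics and
    standard error metrics. Includes parameterized synthetic vessel fixtures
    (straight, curved, stenotic tubes) with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
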