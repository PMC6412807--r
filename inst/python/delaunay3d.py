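"""Delaunay tessellation backend (Qhull via scipy).

Usage: python delaunay3d.py points.txt out.txt

points.txt: one "x y z" triple per line.
out.txt:    line 1: "nsimplex hull_volume ncoplanar"
            then one simplex per line as four 0-based vertex indices.

ncoplanar > 0 flags points that Qhull left out of the triangulation
(degenerate input); the caller is expected to jitter and retry.
"""
import sys

import numpy as np
from scipy.spatial import ConvexHull, Delaunay


def main(inp, out):
    pts = np.loadtxt(inp, ndmin=2)
    tri = Delaunay(pts)
    hull = ConvexHull(pts)
    with open(out, "w") as fh:
        fh.write("%d %.17g %d\n" % (tri.nsimplex, hull.volume,
                                    tri.coplanar.shape[0]))
        np.savetxt(fh, tri.simplices, fmt="%d")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
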