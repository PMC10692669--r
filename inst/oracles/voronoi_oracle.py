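"""Independent Voronoi-adjacency oracle.

Reads a CSV of points (columns x, y) and a frame (xmax, ymax; origin 0,0),
computes the Voronoi diagram with scipy, and reports every point pair whose
Voronoi ridge, clipped to the frame rectangle, has positive length. The
shared boundary of two frame-clipped Voronoi cells is exactly the ridge
between their sites intersected with the frame, so this is the clipped
Delaunay-dual adjacency.

Usage: python voronoi_oracle.py points.csv XMAX YMAX out.csv [MIN_LEN]
"""
import sys

import numpy as np
from scipy.spatial import Voronoi
from shapely.geometry import LineString, box


def main() -> None:
    pts_file, xmax, ymax, out = sys.argv[1], float(sys.argv[2]), float(sys.argv[3]), sys.argv[4]
    min_len = float(sys.argv[5]) if len(sys.argv) > 5 else 1e-6
    pts = np.loadtxt(pts_file, delimiter=",", skiprows=1, ndmin=2)
    vor = Voronoi(pts)
    frame = box(0.0, 0.0, xmax, ymax)
    center = pts.mean(axis=0)
    span = max(xmax, ymax) * 100.0
    pairs = []
    for (i, j), rv in zip(vor.ridge_points, vor.ridge_vertices):
        rv = np.asarray(rv)
        if np.all(rv >= 0):
            seg = LineString(vor.vertices[rv])
        else:
            finite = vor.vertices[rv[rv >= 0][0]]
            t = pts[j] - pts[i]
            t = t / np.linalg.norm(t)
            normal = np.array([-t[1], t[0]])
            midpoint = (pts[i] + pts[j]) / 2.0
            direction = np.sign(np.dot(midpoint - center, normal)) * normal
            if np.allclose(direction, 0):
                direction = normal
            seg = LineString([finite, finite + direction * span])
        clipped = seg.intersection(frame)
        if clipped.length > min_len:
            a, b = sorted((int(i) + 1, int(j) + 1))
            pairs.append((a, b))
    pairs.sort()
    with open(out, "w") as fh:
        fh.write("a,b\n")
        for a, b in pairs:
            fh.write(f"{a},{b}\n")


if __name__ == "__main__":
    main()
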