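{
  "name": "FAK_Ph4_12_synthetic",
  "points": [
    {
      "kind": "ACC",
      "x": 6.3,
      "y": 0.2,
      "z": 0.4,
      "radius": 1,
      "essential": true,
      "label": "F1:Acc",
      "annotation": "DFG Asp564"
    },
    {
      "kind": "ACC",
      "x": 0,
      "y": 0,
      "z": 0,
      "radius": 1,
      "essential": true,
      "label": "F2:Acc",
      "annotation": "hinge Cys502"
    },
    {
      "kind": "DON",
      "x": 8.8,
      "y": 1.7,
      "z": -0.6,
      "radius": 1.1,
      "essential": true,
      "label": "F3:Don",
      "annotation": "alpha-C Glu471"
    },
    {
      "kind": "HYD",
      "x": 10.4,
      "y": -1,
      "z": 0.7,
      "radius": 1.4,
      "essential": true,
      "label": "F4:Hyd",
      "annotation": "back pocket (proximal)"
    },
    {
      "kind": "HYD",
      "x": 12.6,
      "y": 0.9,
      "z": -0.4,
      "radius": 1.3,
      "essential": false,
      "label": "F5:Hyd",
      "annotation": "back pocket (distal)"
    }
  ],
  "exclusions": [
    {
      "x": -3.9,
      "y": -2.8,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": -3.9,
      "y": -0.7,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": -3.9,
      "y": -0.7,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": -3.9,
      "y": 1.4,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": -3.9,
      "y": 3.5,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": -1.8,
      "y": -2.8,
      "z": -4.5,
      "radius": 1.2
    },
    {
      "x": -1.8,
      "y": -2.8,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": -1.8,
      "y": -0.7,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": -1.8,
      "y": 1.4,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": -1.8,
      "y": 3.5,
      "z": -4.5,
      "radius": 1.2
    },
    {
      "x": -1.8,
      "y": 3.5,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": 0.3,
      "y": -4.9,
      "z": -0.3,
      "radius": 1.2
    },
    {
      "x": 0.3,
      "y": -2.8,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": 0.3,
      "y": -0.7,
      "z": -4.5,
      "radius": 1.2
    },
    {
      "x": 0.3,
      "y": 1.4,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": 0.3,
      "y": 3.5,
      "z": -4.5,
      "radius": 1.2
    },
    {
      "x": 0.3,
      "y": 3.5,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": 2.4,
      "y": -4.9,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": 2.4,
      "y": -2.8,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": 2.4,
      "y": -2.8,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": 2.4,
      "y": -0.7,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": 2.4,
      "y": 1.4,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": 2.4,
      "y": 3.5,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": 2.4,
      "y": 3.5,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": 4.5,
      "y": -2.8,
      "z": -0.3,
      "radius": 1.2
    },
    {
      "x": 4.5,
      "y": -0.7,
      "z": -4.5,
      "radius": 1.2
    },
    {
      "x": 4.5,
      "y": -0.7,
      "z": 6,
      "radius": 1.2
    },
    {
      "x": 4.5,
      "y": 1.4,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": 4.5,
      "y": 3.5,
      "z": -0.3,
      "radius": 1.2
    },
    {
      "x": 4.5,
      "y": 5.6,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": 6.6,
      "y": -4.9,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": 6.6,
      "y": -2.8,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": 6.6,
      "y": -0.7,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": 6.6,
      "y": 1.4,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": 6.6,
      "y": 3.5,
      "z": -4.5,
      "radius": 1.2
    },
    {
      "x": 6.6,
      "y": 3.5,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": 6.6,
      "y": 5.6,
      "z": -0.3,
      "radius": 1.2
    },
    {
      "x": 8.7,
      "y": -4.9,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": 8.7,
      "y": -2.8,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": 8.7,
      "y": -2.8,
      "z": 6,
      "radius": 1.2
    },
    {
      "x": 8.7,
      "y": -0.7,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": 8.7,
      "y": 1.4,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": 8.7,
      "y": 3.5,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": 8.7,
      "y": 5.6,
      "z": -0.3,
      "radius": 1.2
    },
    {
      "x": 10.8,
      "y": -4.9,
      "z": -0.3,
      "radius": 1.2
    },
    {
      "x": 10.8,
      "y": -2.8,
      "z": -4.5,
      "radius": 1.2
    },
    {
      "x": 10.8,
      "y": -0.7,
      "z": -4.5,
      "radius": 1.2
    },
    {
      "x": 10.8,
      "y": -0.7,
      "z": 6,
      "radius": 1.2
    },
    {
      "x": 10.8,
      "y": 1.4,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": 10.8,
      "y": 3.5,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": 10.8,
      "y": 5.6,
      "z": -4.5,
      "radius": 1.2
    },
    {
      "x": 10.8,
      "y": 5.6,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": 12.9,
      "y": -4.9,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": 12.9,
      "y": -2.8,
      "z": -0.3,
      "radius": 1.2
    },
    {
      "x": 12.9,
      "y": -0.7,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": 12.9,
      "y": 1.4,
      "z": -4.5,
      "radius": 1.2
    },
    {
      "x": 12.9,
      "y": 3.5,
      "z": -4.5,
      "radius": 1.2
    },
    {
      "x": 12.9,
      "y": 3.5,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": 12.9,
      "y": 5.6,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": 15,
      "y": -2.8,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": 15,
      "y": -0.7,
      "z": -0.3,
      "radius": 1.2
    },
    {
      "x": 15,
      "y": 1.4,
      "z": -2.4,
      "radius": 1.2
    },
    {
      "x": 15,
      "y": 1.4,
      "z": 3.9,
      "radius": 1.2
    },
    {
      "x": 15,
      "y": 3.5,
      "z": 1.8,
      "radius": 1.2
    },
    {
      "x": 15,
      "y": 5.6,
      "z": -0.3,
      "radius": 1.2
    },
    {
      "x": 17.1,
      "y": -0.7,
      "z": -0.3,
      "radius": 1.2
    },
    {
      "x": 17.1,
      "y": 1.4,
      "z": -0.3,
      "radius": 1.2
    },
    {
      "x": 17.1,
      "y": 3.5,
      "z": 1.8,
      "radius": 1.2
    }
  ],
  "provenance": "Synthetic reconstruction: published feature inventory (5 features, 68 excluded volumes) at plausible type II kinase-site geometry; NOT the published coordinates."
}
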