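{
  "schemaVersion": 2,
  "metadata": {
    "displayName": "Synthetic camera pick-and-place rack",
    "displayCategory": "other",
    "displayVolumeUnits": "uL"
  },
  "parameters": {
    "loadName": "synthetic_camera_rack_6pos",
    "format": "irregular",
    "isTiprack": false
  },
  "dimensions": {
    "xDimension": 128,
    "yDimension": 85,
    "zDimension": 60
  },
  "ordering": [
    ["A1", "B1"],
    ["A2", "B2"],
    ["A3", "B3"]
  ],
  "wells": {
    "A1": {
      "x": 24,
      "y": 22.5,
      "z": 0,
      "depth": 60,
      "totalLiquidVolume": 0,
      "shape": "circular"
    },
    "B1": {
      "x": 24,
      "y": 62.5,
      "z": 0,
      "depth": 60,
      "totalLiquidVolume": 0,
      "shape": "circular"
    },
    "A2": {
      "x": 64,
      "y": 22.5,
      "z": 0,
      "depth": 60,
      "totalLiquidVolume": 0,
      "shape": "circular"
    },
    "B2": {
      "x": 64,
      "y": 62.5,
      "z": 0,
      "depth": 60,
      "totalLiquidVolume": 0,
      "shape": "circular"
    },
    "A3": {
      "x": 104,
      "y": 22.5,
      "z": 0,
      "depth": 60,
      "totalLiquidVolume": 0,
      "shape": "circular"
    },
    "B3": {
      "x": 104,
      "y": 62.5,
      "z": 0,
      "depth": 60,
      "totalLiquidVolume": 0,
      "shape": "circular"
    }
  }
}
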