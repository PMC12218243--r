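{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {"code": "TOYA", "name": "Toy subtropical gyre A"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[-60, 10], [-20, 10], [-20, 40], [-60, 40], [-60, 10]]]
      }
    },
    {
      "type": "Feature",
      "properties": {"code": "TOYB", "name": "Toy equatorial band B"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[-60, -10], [-20, -10], [-20, 10], [-60, 10], [-60, -10]]]
      }
    },
    {
      "type": "Feature",
      "properties": {"code": "TOYC", "name": "Toy southern province C"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[100, -60], [160, -60], [160, -30], [100, -30], [100, -60]]]
      }
    }
  ]
}
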