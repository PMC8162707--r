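{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {
        "name": "Greenland",
        "synthetic": true,
        "note": "Coarse hand-digitised outline (~30 vertices), a synthetic stand-in for a full-resolution coastline; adequate for 25-km route sampling and the 100-km inland threshold.",
        "reroute_waypoints": {"Cape Farewell": [59.77, -43.93]}
      },
      "geometry": {
        "type": "Polygon",
        "coordinates": [[
          [-44.0, 60.1],
          [-46.5, 60.7],
          [-48.2, 61.5],
          [-49.8, 63.0],
          [-51.5, 64.2],
          [-53.3, 66.3],
          [-53.8, 68.3],
          [-54.8, 69.8],
          [-55.8, 71.3],
          [-56.5, 72.8],
          [-58.5, 74.5],
          [-63.0, 75.8],
          [-66.5, 76.2],
          [-68.5, 76.6],
          [-72.0, 78.2],
          [-68.0, 80.2],
          [-60.0, 81.8],
          [-45.0, 83.0],
          [-30.0, 83.5],
          [-20.0, 82.0],
          [-17.0, 80.0],
          [-20.0, 77.5],
          [-18.0, 75.0],
          [-20.0, 73.0],
          [-22.0, 70.5],
          [-25.5, 68.6],
          [-30.0, 68.0],
          [-33.0, 66.5],
          [-37.5, 65.7],
          [-40.5, 63.5],
          [-42.5, 61.5],
          [-43.5, 60.5],
          [-44.0, 60.1]
        ]]
      }
    }
  ]
}
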