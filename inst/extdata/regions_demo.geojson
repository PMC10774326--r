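{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"name":"CEP","note":"approximate demo rectangle, not an authoritative management-unit boundary"},"geometry":{"type":"Polygon","coordinates":[[[-120,-5],[-75,-5],[-75,18],[-120,18],[-120,-5]]]}},{"type":"Feature","properties":{"name":"NWA","note":"approximate demo rectangle, not an authoritative management-unit boundary"},"geometry":{"type":"Polygon","coordinates":[[[-100,18.001],[-55,18.001],[-55,35],[-100,35],[-100,18.001]]]}},{"type":"Feature","properties":{"name":"SWA","note":"approximate demo rectangle, not an authoritative management-unit boundary"},"geometry":{"type":"Polygon","coordinates":[[[-60,-39],[-30,-39],[-30,0],[-60,0],[-60,-39]]]}},{"type":"Feature","properties":{"name":"CEA","note":"approximate demo rectangle, not an authoritative management-unit boundary"},"geometry":{"type":"Polygon","coordinates":[[[-20,-10],[15,-10],[15,25],[-20,25],[-20,-10]]]}},{"type":"Feature","properties":{"name":"MED","note":"approximate demo rectangle, not an authoritative management-unit boundary"},"geometry":{"type":"Polygon","coordinates":[[[-6,30],[36,30],[36,46],[-6,46],[-6,30]]]}},{"type":"Feature","properties":{"name":"NWI","note":"approximate demo rectangle, not an authoritative management-unit boundary"},"geometry":{"type":"Polygon","coordinates":[[[32,0],[78,0],[78,30],[32,30],[32,0]]]}},{"type":"Feature","properties":{"name":"SWI","note":"approximate demo rectangle, not an authoritative management-unit boundary"},"geometry":{"type":"Polygon","coordinates":[[[20,-39],[60,-39],[60,-0.001],[20,-0.001],[20,-39]]]}},{"type":"Feature","properties":{"name":"NEI","note":"approximate demo rectangle, not an authoritative management-unit boundary"},"geometry":{"type":"Polygon","coordinates":[[[78.001,0],[105,0],[105,30],[78.001,30],[78.001,0]]]}}]}
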