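# Bill of materials: electronics and heating components (prices in EUR).
currency: EUR
items:
  - {name: "Arduino UNO rev 3.0", price: "22.80"}
  - {name: "solderless breadboard (large)", price: "56.65"}
  - {name: "jumper wires", price: "12.99"}
  - {name: "resistors (5)", price: "1.44"}
  - {name: "DC-DC stepdown converter", price: "7.79"}
  - {name: "metal oxide semiconductor field-effect transistor (MOSFET)", price: "1.67"}
  - {name: "bipolar junction transistor", price: "0.46"}
  - {name: "rotary encoder", price: "2.12"}
  - {name: "Arduino I2C liquid crystal display (LCD)", price: "13.47"}
  - {name: "waterblock", price: "10.95"}
  - {name: "polyimide heating strip x 2", price: "6.54"}
  - {name: "K-type thermocouple (1 M) x 2", price: "22.18"}
  - {name: "MAX-6675 thermocouple amplifier x 2", price: "19.04"}
  - {name: "three-dimensional printing costs (excl. printer & filament)", price: "2.00"}
  - {name: "graphite thermal interface sheet", price: "20.90"}
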