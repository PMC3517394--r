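ALDER
BEECH
BIRCH
BRAMBLE
CEDAR
CHESTNUT
CLOVER
COBALT
DOGWOOD
ELDERBERRY
FERNWOOD
FOXGLOVE
GRANITE
HARVEST
HAWTHORN
HICKORY
HOLLYHOCK
IRONWOOD
JUNIPER
KESTREL
LARKSPUR
LAUREL
MAGNOLIA
MARIGOLD
MEADOWLARK
MULBERRY
NIGHTINGALE
OAKMONT
ORCHARD
PERIWINKLE
PINECREST
QUARRY
REDBUD
ROSEWOOD
SASSAFRAS
SYCAMORE
TAMARACK
THISTLE
TRILLIUM
TUPELO
VERBENA
WILLOWBROOK
WINTERBERRY
WOODBINE
YARROW
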