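abundant
acorn
amber
anchor
apple
arrow
aspen
autumn
badge
bamboo
banner
barley
basket
beacon
birch
bison
blossom
breeze
bridge
bronze
brook
butter
cabin
candle
canyon
carbon
cedar
cello
charm
cherry
cinder
citrus
clover
cobalt
comet
copper
coral
cotton
cricket
crystal
dahlia
dapple
delta
denim
drift
ember
falcon
feather
fennel
fern
flint
forest
fossil
garnet
ginger
glacier
goblet
granite
grove
harbor
hazel
heron
hickory
hollow
indigo
iris
ivory
jasper
juniper
kestrel
lagoon
lantern
larch
lichen
lilac
linen
lotus
magnet
mango
maple
marble
meadow
mellow
mineral
mosaic
moss
nectar
nimbus
nutmeg
oasis
ochre
olive
onyx
opal
orchard
osprey
otter
pebble
pepper
pigeon
pine
plume
pollen
poplar
prairie
prism
quartz
quill
raven
reed
ripple
river
russet
saffron
sage
salmon
sandal
sapphire
seashell
sequoia
shadow
silver
sparrow
spruce
summit
sundial
tamarind
tangerine
thistle
timber
topaz
trellis
tulip
tundra
turquoise
umber
velvet
violet
walnut
willow
winter
wren
zephyr
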