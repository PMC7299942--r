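#' @include AllClasses.R
NULL

#' Physical voxel size of a volume
#'
#' @param x a [LabelVolume-class] or [ImageStack-class].
#' @return numeric length-3, voxel edge lengths (x, y, z) in nm.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Replace the voxel size
#' @param x a volume object.
#' @param value numeric length-3 (nm).
#' @export
setGeneric("voxelSize<-", function(x, value) standardGeneric("voxelSize<-"))

#' Raw voxel data of a volume
#' @param x a [LabelVolume-class] or [ImageStack-class].
#' @return the integer array, dim `c(nx, ny, nz)`.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Distinct nonzero labels of a label volume
#' @param x a [LabelVolume-class].
#' @return sorted integer vector of nonzero labels.
#' @export
setGeneric("labelIds", function(x) standardGeneric("labelIds"))

#' Number of beads in a BeadSet
#' @param x a [BeadSet-class].
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))

#' Tower IDs of a TowerSet or LinkTable
#' @param x a [TowerSet-class] or [LinkTable-class].
#' @export
setGeneric("towerIds", function(x) standardGeneric("towerIds"))

#' Resize a volume, preserving its physical extent
#'
#' @param vol a [LabelVolume-class] or [ImageStack-class].
#' @param factor scalar in (0, 1]; the xy dimensions are scaled by this
#'   amount (label volumes by nearest-neighbour resampling, image stacks by
#'   area averaging) and the voxel size is rescaled so the physical extent
#'   is preserved.
#' @param resizeZ also scale the z axis (default FALSE; the milling step is
#'   already coarse relative to the xy pixel).
#' @return an object of the same class.
#' @export
setGeneric("resizeVolume", function(vol, factor, resizeZ = FALSE)
    standardGeneric("resizeVolume"))

#' Crop a volume to an axis-aligned voxel box
#'
#' @param vol a [LabelVolume-class] or [ImageStack-class].
#' @param box list with integer length-2 elements `x`, `y`, `z` giving
#'   inclusive 1-based index ranges.
#' @return the subvolume; the voxel size is unchanged.
#' @export
setGeneric("cropVolume", function(vol, box) standardGeneric("cropVolume"))
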